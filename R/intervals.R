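#' Interval sets on a consensus sequence
#'
#' All overlap logic in the package runs on *interval sets*: tibbles with
#' integer columns `start` and `end` holding 0-based half-open intervals
#' `[start, end)` on a single axis (a consensus sequence or a contig).
#' A normalized interval set is sorted and pairwise disjoint; overlapping or
#' touching intervals are merged. Normalisation and set algebra are delegated
#' to [IRanges::IRanges-class] internally; tibbles are the user-facing
#' representation so results print and join naturally.
#'
#' @param start,end Integer vectors of equal length; each pair must satisfy
#'   `0 <= start < end`.
#' @return A normalized interval-set tibble with columns `start`, `end`.
#' @examples
#' interval_set(c(10, 40), c(50, 80))   # overlapping -> one interval [10, 80)
#' interval_set(c(10, 50), c(50, 80))   # touching    -> one interval [10, 80)
#' @export
interval_set <- function(start = integer(), end = integer()) {
  start <- as.integer(start)
  end <- as.integer(end)
  if (length(start) != length(end)) {
    stop("`start` and `end` must have equal length", call. = FALSE)
  }
  if (anyNA(start) || anyNA(end)) {
    stop("intervals must not contain NA", call. = FALSE)
  }
  if (any(end <= start)) {
    bad <- which(end <= start)[1]
    stop(sprintf("interval %d is empty or reversed: [%d, %d)", bad,
                 start[bad], end[bad]), call. = FALSE)
  }
  if (any(start < 0)) {
    stop("interval starts must be >= 0", call. = FALSE)
  }
  as_tbl0(IRanges::reduce(ir0(tibble(start = start, end = end))))
}

# 0-based half-open tibble -> 1-based closed IRanges (internal)
ir0 <- function(x) {
  IRanges::IRanges(start = as.integer(x$start) + 1L, end = as.integer(x$end))
}

# IRanges -> 0-based half-open tibble (internal)
as_tbl0 <- function(ir) {
  ir <- BiocGenerics::sort(ir)
  tibble(start = BiocGenerics::start(ir) - 1L, end = BiocGenerics::end(ir))
}

#' Merge intervals that overlap, touch, or lie within a gap
#'
#' @param x An interval-set tibble (`start`, `end`; 0-based half-open).
#' @param gap_max Non-negative integer; intervals separated by at most this
#'   many uncovered positions are coalesced. `0` merges only overlapping or
#'   touching intervals.
#' @return A normalized interval-set tibble.
#' @examples
#' merge_intervals(tibble::tibble(start = c(10, 55), end = c(50, 80)), gap_max = 30)
#' @export
merge_intervals <- function(x, gap_max = 0L) {
  gap_max <- as.integer(gap_max)
  if (is.na(gap_max) || gap_max < 0L) {
    stop("`gap_max` must be a non-negative integer", call. = FALSE)
  }
  if (nrow(x) == 0) return(tibble(start = integer(), end = integer()))
  as_tbl0(IRanges::reduce(ir0(x), min.gapwidth = gap_max + 1L))
}

#' Interval-set difference, intersection, and union
#'
#' Set algebra on normalized interval sets; all inputs and outputs are
#' 0-based half-open tibbles.
#'
#' @param a,b Interval-set tibbles.
#' @return A normalized interval-set tibble.
#' @export
interval_diff <- function(a, b) {
  if (nrow(a) == 0) return(tibble(start = integer(), end = integer()))
  if (nrow(b) == 0) return(merge_intervals(a))
  as_tbl0(IRanges::setdiff(ir0(a), ir0(b)))
}

#' @rdname interval_diff
#' @export
interval_intersect <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(tibble(start = integer(), end = integer()))
  }
  as_tbl0(IRanges::intersect(ir0(a), ir0(b)))
}

#' @rdname interval_diff
#' @export
interval_union <- function(a, b) {
  merge_intervals(bind_rows(
    tibble(start = as.integer(a$start), end = as.integer(a$end)),
    tibble(start = as.integer(b$start), end = as.integer(b$end))
  ))
}

#' Total number of positions covered by an interval set
#'
#' @param x An interval-set tibble.
#' @return Integer: `sum(end - start)` after normalization.
#' @export
interval_width <- function(x) {
  if (nrow(x) == 0) return(0L)
  x <- merge_intervals(x)
  sum(x$end - x$start)
}
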