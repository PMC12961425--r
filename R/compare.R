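#' Read TE annotations from BED or GFF3
#'
#' Features are normalized to 0-based half-open intervals (GFF3's 1-based
#' inclusive coordinates are converted). The TE classification is taken
#' from the BED name column or the GFF3 `Name` (else `ID`) attribute and
#' split on `/` into high and sub levels; features without a usable name
#' are `Unknown`. Within a method, overlapping features of the same class
#' on the same sequence are merged before comparison.
#'
#' @param path Path to the annotation file.
#' @param format `"bed"`, `"gff3"`, or `"auto"` (by file extension).
#' @param method Label identifying the annotation method.
#' @return A feature tibble: `seqid`, `start`, `end` (0-based half-open),
#'   `class_high`, `class_sub`, `method`.
#' @export
read_annotations <- function(path, format = c("auto", "bed", "gff3"),
                             method = "method") {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed"
      else if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3"
      else stop(sprintf("cannot infer format of '%s'; pass format=", path),
                call. = FALSE)
  }
  gr <- rtracklayer::import(path, format = if (format == "gff3") "gff3" else "bed")
  if (any(BiocGenerics::width(gr) < 1)) {
    stop("annotation with end < start encountered", call. = FALSE)
  }
  nm <- if (format == "bed") {
    if ("name" %in% names(S4Vectors::mcols(gr))) S4Vectors::mcols(gr)$name
    else rep(NA_character_, length(gr))
  } else {
    mc <- S4Vectors::mcols(gr)
    nm <- if ("Name" %in% names(mc)) as.character(mc$Name)
      else rep(NA_character_, length(gr))
    if ("ID" %in% names(mc)) {
      id <- as.character(mc$ID)
      nm[is.na(nm)] <- id[is.na(nm)]
    }
    nm
  }
  nm[is.na(nm) | !nzchar(nm)] <- "Unknown"
  parts <- strsplit(nm, "/", fixed = TRUE)
  feats <- tibble(
    seqid = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    class_high = vapply(parts, `[`, character(1), 1),
    class_sub = vapply(parts, function(p) {
      if (length(p) > 1) p[2] else NA_character_
    }, character(1)),
    method = method
  )
  # merge within method per (seqid, class)
  feats |>
    group_by(seqid, class_high, class_sub, method) |>
    dplyr::reframe(merge_intervals(tibble(start = start, end = end))) |>
    arrange(seqid, start) |>
    select(seqid, start, end, class_high, class_sub, method)
}

# per-seqid reduced IRanges from a feature tibble (internal); strand is
# ignored: repeat annotations are compared as genomic extents
feat_ranges <- function(x, seqids) {
  out <- setNames(vector("list", length(seqids)), seqids)
  idx <- split(seq_len(nrow(x)), factor(x$seqid, levels = seqids))
  for (sid in seqids) {
    i <- idx[[sid]]
    out[[sid]] <- IRanges::reduce(
      IRanges::IRanges(start = x$start[i] + 1L, end = x$end[i]))
  }
  out
}

ir_width <- function(ir) sum(ir@width)

# summed widths of three-way accounting across a list of seqids (internal)
ranges_accounting <- function(ra, rb) {
  shared <- 0L; only_a <- 0L; only_b <- 0L
  hit_a <- 0L; hit_b <- 0L
  for (sid in names(ra)) {
    ga <- ra[[sid]]; gb <- rb[[sid]]
    shared <- shared + ir_width(IRanges::intersect(ga, gb))
    only_a <- only_a + ir_width(IRanges::setdiff(ga, gb))
    only_b <- only_b + ir_width(IRanges::setdiff(gb, ga))
    hit_a <- hit_a + ir_width(ga[IRanges::overlapsAny(ga, gb)])
    hit_b <- hit_b + ir_width(gb[IRanges::overlapsAny(gb, ga)])
  }
  list(shared = shared, only_a = only_a, only_b = only_b,
       hit_a = hit_a, hit_b = hit_b)
}

#' Compare two TE annotation sets at base-pair resolution
#'
#' Quantifies agreement between two annotation methods on one genome in
#' two accountings. *Position-level* (the default invariant-bearing one):
#' genomic positions covered by both methods are `shared`, positions
#' covered by only one are `unique_A` / `unique_B`; the three categories
#' partition all annotated positions and their percentages sum to 100.
#' *Width-level* at shared loci: for the shared category the width of each
#' method's own merged annotations overlapping the other method is
#' reported separately (`bp_A`, `bp_B`), because annotation extents can
#' differ between methods at the same locus. A per-class breakdown
#' restricted to each `class_high` of the owning method is included.
#'
#' @param a_features,b_features Feature tibbles from [read_annotations()].
#' @return A list of class `te_comparison` with tibbles `positions`
#'   (`category`, `bp`, `pct`), `widths` (`category`, `bp_A`, `bp_B`,
#'   `pct`), `by_class` (`method`, `class_high`, `shared_bp`,
#'   `unique_bp`), and `totals` (`method`, `covered_bp`).
#' @export
compare_annotations <- function(a_features, b_features) {
  seqids <- sort(unique(c(a_features$seqid, b_features$seqid)))
  ra <- feat_ranges(a_features, seqids)
  rb <- feat_ranges(b_features, seqids)
  acc <- ranges_accounting(ra, rb)

  pos_bp <- c(shared = acc$shared, unique_A = acc$only_a,
              unique_B = acc$only_b)
  all_bp <- sum(pos_bp)
  positions <- tibble(
    category = names(pos_bp), bp = as.integer(pos_bp),
    pct = if (all_bp > 0) 100 * pos_bp / all_bp else rep(0, 3)
  )

  w <- tibble(
    category = c("shared", "unique_A", "unique_B"),
    bp_A = as.integer(c(acc$hit_a, acc$only_a, 0L)),
    bp_B = as.integer(c(acc$hit_b, 0L, acc$only_b))
  )
  w_total <- sum(w$bp_A + w$bp_B)
  widths <- mutate(w, pct = if (w_total > 0) {
    100 * (bp_A + bp_B) / w_total
  } else 0)

  per_class <- function(x, other, label) {
    cl <- split(seq_len(nrow(x)), x$class_high)
    out <- lapply(names(cl), function(k) {
      g <- feat_ranges(x[cl[[k]], , drop = FALSE], seqids)
      shared_bp <- 0L; unique_bp <- 0L
      for (sid in seqids) {
        shared_bp <- shared_bp +
          ir_width(IRanges::intersect(g[[sid]], other[[sid]]))
        unique_bp <- unique_bp +
          ir_width(IRanges::setdiff(g[[sid]], other[[sid]]))
      }
      tibble(method = label, class_high = k,
             shared_bp = as.integer(shared_bp),
             unique_bp = as.integer(unique_bp))
    })
    bind_rows(out)
  }
  lab_a <- if (nrow(a_features)) a_features$method[1] else "A"
  lab_b <- if (nrow(b_features)) b_features$method[1] else "B"
  by_class <- bind_rows(per_class(a_features, rb, lab_a),
                        per_class(b_features, ra, lab_b))

  totals <- tibble(
    method = c(lab_a, lab_b),
    covered_bp = as.integer(c(
      sum(vapply(ra, ir_width, numeric(1))),
      sum(vapply(rb, ir_width, numeric(1))))))

  structure(list(positions = positions, widths = widths,
                 by_class = by_class, totals = totals),
            class = "te_comparison")
}

#' @export
print.te_comparison <- function(x, ...) {
  cat("TE annotation comparison (position-level accounting):\n")
  print(x$positions)
  cat("\nWidths at shared loci (per-method extents):\n")
  print(x$widths)
  invisible(x)
}

#' Write a comparison summary
#'
#' @param x A `te_comparison` object.
#' @param path Output path (`.json` for the machine-readable summary,
#'   anything else for TSV of the position-level table).
#' @return `path`, invisibly.
#' @export
write_comparison <- function(x, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(lapply(unclass(x), as.data.frame), path,
                         auto_unbox = TRUE, digits = NA)
  } else {
    readr::write_tsv(x$positions, path, progress = FALSE)
  }
  invisible(path)
}
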