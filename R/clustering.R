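#' Clustering parameters for the 80-80-80 family rule
#'
#' Two consensus sequences belong to one TE family when they align at
#' >= 80% identity over >= 80% of the shorter sequence and both are at
#' least 80 bp long. Alignment scoring follows the usual nucleotide local
#' alignment defaults (match +1, mismatch -1, gap open -2, gap extend -1);
#' both strands are compared because TE families occur in either
#' orientation.
#'
#' @param min_identity Minimum alignment identity (matches / alignment
#'   columns).
#' @param min_coverage Minimum aligned fraction of the shorter sequence.
#' @param min_length_nt Minimum sequence length for clustering.
#' @param match,mismatch,gap_open,gap_ext Alignment scoring parameters
#'   (penalties positive for gaps).
#' @param check_revcomp Also try the reverse complement and keep the better
#'   strand.
#' @return A list of class `cluster_params`.
#' @export
cluster_params <- function(min_identity = 0.80, min_coverage = 0.80,
                           min_length_nt = 80L, match = 1, mismatch = -1,
                           gap_open = 2, gap_ext = 1, check_revcomp = TRUE) {
  stopifnot(min_identity > 0, min_identity <= 1,
            min_coverage > 0, min_coverage <= 1, min_length_nt > 0)
  structure(list(min_identity = min_identity, min_coverage = min_coverage,
                 min_length_nt = as.integer(min_length_nt), match = match,
                 mismatch = mismatch, gap_open = gap_open, gap_ext = gap_ext,
                 check_revcomp = check_revcomp),
            class = "cluster_params")
}

# substitution matrix over {A,C,G,T,N}; N never matches (internal)
nt_submat <- function(match, mismatch) {
  letters <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(letters, letters))
  diag(m) <- match
  m["N", "N"] <- mismatch
  m
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Pairwise identity and short-sequence coverage
#'
#' Computes the best local alignment between two nucleotide sequences
#' (via [Biostrings::pairwiseAlignment()]) on both strands and reports the
#' two fractions the 80-80-80 rule tests: identity (matches divided by
#' alignment columns, gaps included) and coverage of the shorter sequence
#' (aligned span of the shorter sequence over its length).
#'
#' @param a,b Nucleotide sequences (character).
#' @param params A [cluster_params()] object.
#' @return A list with `identity`, `coverage_short`, `score`, and `strand`
#'   (`"+"` or `"-"` for the reverse complement of `b`).
#' @examples
#' pairwise_identity_coverage("ACGTACGTACGT", "ACGTACGTACGT")
#' @export
pairwise_identity_coverage <- function(a, b, params = cluster_params()) {
  stopifnot(nzchar(a), nzchar(b))
  a <- toupper(a); b <- toupper(b)
  mat <- nt_submat(params$match, params$mismatch)
  one <- function(bb) {
    Biostrings::pairwiseAlignment(
      a, bb, type = "local", substitutionMatrix = mat,
      gapOpening = params$gap_open, gapExtension = params$gap_ext)
  }
  aln <- one(b)
  strand <- "+"
  if (params$check_revcomp) {
    aln_rc <- one(revcomp(b))
    if (Biostrings::score(aln_rc) > Biostrings::score(aln)) {
      aln <- aln_rc
      strand <- "-"
    }
  }
  columns <- Biostrings::nchar(aln)
  identity <- if (columns == 0) 0 else Biostrings::nmatch(aln) / columns
  short_is_a <- nchar(a) <= nchar(b)
  part <- if (short_is_a) Biostrings::pattern(aln) else Biostrings::subject(aln)
  span <- BiocGenerics::end(part) - BiocGenerics::start(part) + 1L
  coverage_short <- span / min(nchar(a), nchar(b))
  list(identity = identity, coverage_short = coverage_short,
       score = Biostrings::score(aln), strand = strand)
}

#' Reference dynamic-programming alignment statistics
#'
#' An independent full-matrix Gotoh local aligner with traceback, used as
#' the brute-force cross-check for alignment-derived quantities (identity,
#' coverage, score). `N` never matches. Quadratic time and memory; intended
#' for verification at desk scale, not production clustering.
#'
#' @param a,b Nucleotide sequences (character).
#' @param match,mismatch,gap_open,gap_ext Scoring as in [cluster_params()].
#' @return A list with `score`, `matches`, `columns`, and the 1-based
#'   inclusive aligned spans `a_start`/`a_end`, `b_start`/`b_end`.
#' @export
dp_align_stats <- function(a, b, match = 1, mismatch = -1, gap_open = 2,
                           gap_ext = 1) {
  .sw_align(toupper(a), toupper(b), match = match, mismatch = mismatch,
            gap_open = gap_open, gap_ext = gap_ext)
}

#' Greedy 80-80-80 family clustering
#'
#' Reference implementation of family clustering for desk-scale libraries,
#' in the greedy longest-first style of CD-HIT: records are sorted by
#' length (descending, ties by id) and each joins the first existing
#' cluster whose *representative* it matches at `min_identity` and
#' `min_coverage` on either strand, otherwise it founds a new cluster.
#' Large libraries should be clustered with a dedicated external tool
#' whose two-column cluster table this output matches (see
#' [read_cluster_table()]).
#'
#' @param library A library tibble (`record_id`, `sequence`); every record
#'   must be at least `min_length_nt` long.
#' @param params A [cluster_params()] object.
#' @return A cluster tibble with columns `representative_id`, `member_id`
#'   (representatives listed as their own members); clusters partition the
#'   input ids.
#' @export
greedy_cluster <- function(library, params = cluster_params()) {
  too_short <- library$record_id[nchar(library$sequence) < params$min_length_nt]
  if (length(too_short)) {
    stop(sprintf("record(s) below the %d bp clustering minimum: %s",
                 params$min_length_nt, paste(too_short, collapse = ", ")),
         call. = FALSE)
  }
  ord <- order(-nchar(library$sequence), library$record_id)
  ids <- library$record_id[ord]
  seqs <- toupper(library$sequence[ord])
  rep_id <- character(0)
  rep_seq <- character(0)
  assignment <- character(length(ids))
  for (i in seq_along(ids)) {
    joined <- NA_integer_
    for (k in seq_along(rep_id)) {
      st <- pairwise_identity_coverage(seqs[i], rep_seq[k], params)
      if (st$identity >= params$min_identity &&
          st$coverage_short >= params$min_coverage) {
        joined <- k
        break
      }
    }
    if (is.na(joined)) {
      rep_id <- c(rep_id, ids[i])
      rep_seq <- c(rep_seq, seqs[i])
      assignment[i] <- ids[i]
    } else {
      assignment[i] <- rep_id[joined]
    }
  }
  tibble(representative_id = assignment, member_id = ids) |>
    arrange(representative_id, member_id)
}

#' Read or write a two-column cluster table
#'
#' The TSV interchange format shared with external clustering tools: one
#' row per member, columns `representative_id` and `member_id` (no header
#' on disk, matching the common external output). An external clusterer
#' adapter only needs to produce this table from a FASTA and the
#' [cluster_params()] to be interchangeable with [greedy_cluster()].
#'
#' @param path Path to the table.
#' @return A cluster tibble.
#' @export
read_cluster_table <- function(path) {
  readr::read_tsv(path, col_names = c("representative_id", "member_id"),
                  col_types = "cc", show_col_types = FALSE, progress = FALSE)
}

#' @rdname read_cluster_table
#' @param clusters A cluster tibble.
#' @return `path`, invisibly.
#' @export
write_cluster_table <- function(clusters, path) {
  readr::write_tsv(clusters[, c("representative_id", "member_id")], path,
                   col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Verify cluster membership against the family rule
#'
#' Re-checks every member against its representative with a supplied
#' aligner (by default the independent DP reference, [dp_align_stats()]),
#' returning one row per member with the measured identity and coverage
#' and whether the acceptance rule holds.
#'
#' @param clusters A cluster tibble.
#' @param library The library tibble the clusters came from.
#' @param params A [cluster_params()] object.
#' @return A tibble with `representative_id`, `member_id`, `identity`,
#'   `coverage_short`, `ok`.
#' @export
verify_clusters <- function(clusters, library, params = cluster_params()) {
  seqs <- setNames(toupper(library$sequence), library$record_id)
  out <- lapply(seq_len(nrow(clusters)), function(i) {
    rep_id <- clusters$representative_id[i]
    mem_id <- clusters$member_id[i]
    if (rep_id == mem_id) {
      return(tibble(representative_id = rep_id, member_id = mem_id,
                    identity = 1, coverage_short = 1, ok = TRUE))
    }
    a <- seqs[[mem_id]]; b <- seqs[[rep_id]]
    st_f <- dp_align_stats(a, b, params$match, params$mismatch,
                           params$gap_open, params$gap_ext)
    st_r <- if (params$check_revcomp) {
      dp_align_stats(a, revcomp(b), params$match, params$mismatch,
                     params$gap_open, params$gap_ext)
    } else st_f
    st <- if (st_r$score > st_f$score) st_r else st_f
    identity <- if (st$columns == 0) 0 else st$matches / st$columns
    short_len <- min(nchar(a), nchar(b))
    span <- if (nchar(a) <= nchar(b)) {
      st$a_end - st$a_start + 1L
    } else {
      st$b_end - st$b_start + 1L
    }
    cov <- if (st$columns == 0) 0 else span / short_len
    tibble(representative_id = rep_id, member_id = mem_id,
           identity = identity, coverage_short = cov,
           ok = identity >= params$min_identity &&
             cov >= params$min_coverage)
  })
  bind_rows(out)
}
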