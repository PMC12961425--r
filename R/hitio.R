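#' Hit-filtering thresholds
#'
#' Defaults follow the stringent settings used for large-scale fungal TE
#' library curation: host-protein (RefSeq) and TE-peptide BLASTp/DIAMOND
#' hits are kept at e-value <= 1e-3; HMM hits are kept at full-sequence
#' e-value <= 1e-3 *and* full-sequence bit score >= 50. All comparisons are
#' inclusive.
#'
#' @param host_evalue_max,hmm_evalue_max,pep_evalue_max Maximum e-values per
#'   subject category.
#' @param hmm_bitscore_min Minimum full-sequence bit score for HMM hits.
#' @return A list of class `hit_thresholds`.
#' @export
hit_thresholds <- function(host_evalue_max = 1e-3, hmm_evalue_max = 1e-3,
                           hmm_bitscore_min = 50, pep_evalue_max = 1e-3) {
  stopifnot(host_evalue_max > 0, hmm_evalue_max > 0, pep_evalue_max > 0,
            hmm_bitscore_min >= 0)
  structure(list(host_evalue_max = host_evalue_max,
                 hmm_evalue_max = hmm_evalue_max,
                 hmm_bitscore_min = hmm_bitscore_min,
                 pep_evalue_max = pep_evalue_max),
            class = "hit_thresholds")
}

hit_categories <- c("HOST_REFSEQ", "TE_HMM", "TE_PEP")

empty_hits <- function() {
  tibble(
    consensus_id = character(), frame = integer(),
    q_start = integer(), q_end = integer(),
    subject_id = character(), category = character(),
    subject_class_high = character(), subject_class_sub = character(),
    evalue = numeric(), bitscore = numeric(),
    nt_start = integer(), nt_end = integer()
  )
}

# "cons7_5" -> list(id = "cons7", frame = 5); error on unparseable suffix
split_frame_suffix <- function(qseqid) {
  m <- regexec("^(.*)_([1-6])$", qseqid)
  parts <- regmatches(qseqid, m)
  bad <- lengths(parts) == 0
  if (any(bad)) {
    stop(sprintf("query id '%s' has no frame suffix (_1.._6)",
                 qseqid[which(bad)[1]]), call. = FALSE)
  }
  list(id = vapply(parts, `[`, character(1), 2),
       frame = as.integer(vapply(parts, `[`, character(1), 3)))
}

#' Read protein hits from 12-column tabular BLAST/DIAMOND output
#'
#' Parses the standard `outfmt 6` table (qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore). The query id
#' must carry a translation-frame suffix (`<consensus_id>_<frame>`, frame
#' 1-6) as produced by six-frame translators. Query coordinates (1-based
#' inclusive, swapped if reversed) become a 0-based half-open residue span.
#'
#' @param path Path to the tabular file.
#' @param category Subject category to stamp on every hit: `"HOST_REFSEQ"`
#'   for reference-proteome subjects, `"TE_PEP"` for TE peptide libraries,
#'   `"TE_HMM"` if the table was derived from profile searches.
#' @return A hit tibble (`consensus_id`, `frame`, `q_start`, `q_end`,
#'   `subject_id`, `category`, `evalue`, `bitscore`, ...); `nt_start`/
#'   `nt_end` are NA until [project_hits()] is applied.
#' @export
read_blast_hits <- function(path, category = c("HOST_REFSEQ", "TE_PEP",
                                               "TE_HMM")) {
  category <- match.arg(category)
  nfields <- count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (length(nfields) == 0) return(empty_hits())
  if (any(nfields != 12)) {
    i <- which(nfields != 12)[1]
    stop(sprintf("line %d of '%s': expected 12 tab-separated columns, found %d",
                 i, path, nfields[i]), call. = FALSE)
  }
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  tab <- readr::read_tsv(path, col_names = cols, show_col_types = FALSE,
                         progress = FALSE,
                         col_types = readr::cols(
                           qseqid = "c", sseqid = "c",
                           .default = readr::col_double()))
  qf <- split_frame_suffix(tab$qseqid)
  tibble(
    consensus_id = qf$id,
    frame = qf$frame,
    q_start = as.integer(pmin(tab$qstart, tab$qend)) - 1L,
    q_end = as.integer(pmax(tab$qstart, tab$qend)),
    subject_id = tab$sseqid,
    category = category,
    subject_class_high = NA_character_,
    subject_class_sub = NA_character_,
    evalue = tab$evalue,
    bitscore = tab$bitscore,
    nt_start = NA_integer_,
    nt_end = NA_integer_
  )
}

#' Read TE-profile hits from a HMMER per-domain table
#'
#' Parses `--domtblout` output of `hmmscan` run on translated consensus
#' frames: one hit per domain line, category `TE_HMM`. The full-sequence
#' E-value and score columns supply `evalue`/`bitscore` (the quantities the
#' curation thresholds apply to); the envelope coordinates (1-based
#' inclusive) supply the residue span. Lines starting with `#` are comments.
#'
#' @param path Path to the domain table.
#' @return A hit tibble as in [read_blast_hits()].
#' @export
read_domtbl_hits <- function(path) {
  lines <- readLines(path)
  keep <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  if (length(keep) == 0) return(empty_hits())
  fields <- strsplit(trimws(lines[keep]), "[ \t]+")
  short <- lengths(fields) < 22
  if (any(short)) {
    stop(sprintf("line %d of '%s': expected >= 22 whitespace-separated fields, found %d",
                 keep[which(short)[1]], path, lengths(fields)[which(short)[1]]),
         call. = FALSE)
  }
  f <- function(k) vapply(fields, `[`, character(1), k)
  qf <- split_frame_suffix(f(4))
  tibble(
    consensus_id = qf$id,
    frame = qf$frame,
    q_start = as.integer(f(20)) - 1L,
    q_end = as.integer(f(21)),
    subject_id = f(1),
    category = "TE_HMM",
    subject_class_high = NA_character_,
    subject_class_sub = NA_character_,
    evalue = as.numeric(f(7)),
    bitscore = as.numeric(f(8)),
    nt_start = NA_integer_,
    nt_end = NA_integer_
  )
}

#' Filter hits by per-category thresholds
#'
#' `HOST_REFSEQ` hits are kept iff `evalue <= host_evalue_max`; `TE_HMM`
#' hits iff `evalue <= hmm_evalue_max` and `bitscore >= hmm_bitscore_min`;
#' `TE_PEP` hits iff `evalue <= pep_evalue_max`. Comparisons are inclusive
#' and input order is preserved; the operation is idempotent.
#'
#' @param hits A hit tibble.
#' @param th A [hit_thresholds()] object.
#' @return The surviving rows of `hits`.
#' @export
filter_hits <- function(hits, th = hit_thresholds()) {
  stopifnot(inherits(th, "hit_thresholds"))
  keep <- (hits$category == "HOST_REFSEQ" & hits$evalue <= th$host_evalue_max) |
    (hits$category == "TE_HMM" & hits$evalue <= th$hmm_evalue_max &
       hits$bitscore >= th$hmm_bitscore_min) |
    (hits$category == "TE_PEP" & hits$evalue <= th$pep_evalue_max)
  hits[keep, , drop = FALSE]
}

#' Project residue spans of hits to consensus nucleotide coordinates
#'
#' Fills `nt_start`/`nt_end` of a hit tibble by applying [residue_to_nt()]
#' with each hit's frame and the length of its consensus, so hits from
#' different frames become comparable on one axis.
#'
#' @param hits A hit tibble.
#' @param library A library tibble (or a named integer vector of consensus
#'   lengths).
#' @return `hits` with `nt_start`/`nt_end` filled.
#' @export
project_hits <- function(hits, library) {
  if (nrow(hits) == 0) return(hits)
  lengths <- if (is.numeric(library)) {
    library
  } else {
    setNames(nchar(library$sequence), library$record_id)
  }
  missing <- setdiff(unique(hits$consensus_id), names(lengths))
  if (length(missing)) {
    stop(sprintf("hits reference unknown consensus id(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  span <- residue_to_nt(hits$frame, hits$q_start, hits$q_end,
                        unname(lengths[hits$consensus_id]))
  hits$nt_start <- span$nt_start
  hits$nt_end <- span$nt_end
  hits
}

# quality order used for nested-hit resolution: higher bitscore, then lower
# evalue, then longer nt span, then lexicographic subject id
hit_quality_order <- function(hits) {
  order(-hits$bitscore, hits$evalue, -(hits$nt_end - hits$nt_start),
        hits$subject_id)
}

#' Remove nested hits, keeping the highest-quality hit
#'
#' Whenever one hit's nucleotide span is fully contained in another's (on
#' the same consensus and within one subject category), the lower-quality
#' hit is removed; quality is ordered by higher bit score, then lower
#' e-value, then longer span, then lexicographic subject id. The result
#' contains no containment pair.
#'
#' @param hits A hit tibble for a single consensus and subject category,
#'   with `nt_start`/`nt_end` filled (see [project_hits()]).
#' @return The surviving rows of `hits`.
#' @export
resolve_nested <- function(hits) {
  if (nrow(hits) == 0) return(hits)
  if (length(unique(hits$consensus_id)) > 1) {
    stop("resolve_nested() expects hits of a single consensus", call. = FALSE)
  }
  if (length(unique(hits$category)) > 1) {
    stop("resolve_nested() expects hits of a single subject category",
         call. = FALSE)
  }
  if (anyNA(hits$nt_start)) {
    stop("nt spans not filled; call project_hits() first", call. = FALSE)
  }
  ord <- hit_quality_order(hits)
  kept <- integer(0)
  for (i in ord) {
    s <- hits$nt_start[i]; e <- hits$nt_end[i]
    ks <- hits$nt_start[kept]; ke <- hits$nt_end[kept]
    contained <- (s >= ks & e <= ke) | (ks >= s & ke <= e)
    if (!any(contained)) kept <- c(kept, i)
  }
  hits[sort(kept), , drop = FALSE]
}

#' Coalesce adjacent and overlapping hits into coverage intervals
#'
#' Takes the union of the nucleotide spans of a consensus's hits, merging
#' intervals that overlap, touch, or are separated by at most `gap_max_nt`
#' uncovered nucleotides. The default gap of 30 nt (10 residues) bridges
#' short indels or frameshifts between split HSPs of one protein without
#' joining unrelated domains.
#'
#' @param hits A hit tibble for one consensus and subject category, nt spans
#'   filled.
#' @param gap_max_nt Non-negative integer gap tolerance in nucleotides.
#' @return A normalized interval-set tibble (see [interval_set()]).
#' @export
merge_hits <- function(hits, gap_max_nt = 30L) {
  if (as.integer(gap_max_nt) < 0 || is.na(gap_max_nt)) {
    stop("`gap_max_nt` must be non-negative", call. = FALSE)
  }
  if (nrow(hits) == 0) return(tibble(start = integer(), end = integer()))
  if (length(unique(hits$consensus_id)) > 1) {
    stop("merge_hits() expects hits of a single consensus", call. = FALSE)
  }
  if (anyNA(hits$nt_start)) {
    stop("nt spans not filled; call project_hits() first", call. = FALSE)
  }
  merge_intervals(tibble(start = hits$nt_start, end = hits$nt_end),
                  gap_max = gap_max_nt)
}

#' Write a hit tibble as TSV
#'
#' @param hits A hit tibble.
#' @param path Output path; a header row is included.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  readr::write_tsv(hits, path, progress = FALSE)
  invisible(path)
}
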