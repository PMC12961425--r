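#' Curation thresholds
#'
#' Defaults follow the settings used for large multi-genome fungal TE
#' databases: a consensus is a
#' putative host gene when at least 90 RefSeq-aligned residues do not
#' overlap TE-protein alignments; sequences under 120 bp or with >= 5% N
#' are poor quality; consensus sequences from assemblies with N50 below
#' 50 kb *and* BUSCO completeness below 90% are flagged `LQGenome`.
#'
#' @param exclusive_residues_min Minimum RefSeq-exclusive residues for the
#'   host-gene call (branch ii).
#' @param min_length_nt Minimum consensus length in nt (strictly-less-than
#'   removal).
#' @param n_fraction_max Maximum tolerated N fraction (inclusive removal at
#'   the boundary).
#' @param n50_min_bp,busco_complete_min_pct Genome-quality cutoffs for the
#'   `LQGenome` flag.
#' @return A list of class `curation_thresholds`.
#' @export
curation_thresholds <- function(exclusive_residues_min = 90L,
                                min_length_nt = 120L,
                                n_fraction_max = 0.05,
                                n50_min_bp = 50000L,
                                busco_complete_min_pct = 90) {
  stopifnot(exclusive_residues_min > 0, min_length_nt > 0,
            n_fraction_max > 0, n50_min_bp > 0, busco_complete_min_pct > 0)
  structure(list(exclusive_residues_min = as.integer(exclusive_residues_min),
                 min_length_nt = as.integer(min_length_nt),
                 n_fraction_max = n_fraction_max,
                 n50_min_bp = as.integer(n50_min_bp),
                 busco_complete_min_pct = busco_complete_min_pct),
            class = "curation_thresholds")
}

#' Host-gene designation from RefSeq and TE-protein coverage
#'
#' A consensus is designated a putative host gene if either (i) it has
#' RefSeq hits and no TE-protein hits, or (ii) it has both, but the RefSeq
#' coverage not overlapped by TE coverage amounts to at least
#' `exclusive_residues_min` residues. Coverage is compared on the shared
#' consensus nucleotide axis; the exclusive residue count is
#' `floor(exclusive_nt / 3)` because RefSeq and TE hits may sit in
#' different frames.
#'
#' @param refseq_cov,te_cov Interval-set tibbles of RefSeq and TE-protein
#'   coverage in consensus nucleotide coordinates.
#' @param th A [curation_thresholds()] object.
#' @return A list with `host_gene` (logical) and `exclusive_residues`
#'   (integer; RefSeq residues without TE overlap, total RefSeq residues
#'   under branch i).
#' @examples
#' classify_host_gene(interval_set(0, 600), interval_set(447, 780))
#' @export
classify_host_gene <- function(refseq_cov, te_cov,
                               th = curation_thresholds()) {
  if (interval_width(refseq_cov) == 0L) {
    return(list(host_gene = FALSE, exclusive_residues = 0L))
  }
  if (interval_width(te_cov) == 0L) {
    return(list(host_gene = TRUE,
                exclusive_residues = interval_width(refseq_cov) %/% 3L))
  }
  exclusive_nt <- interval_width(interval_diff(refseq_cov, te_cov))
  exclusive_residues <- exclusive_nt %/% 3L
  list(host_gene = exclusive_residues >= th$exclusive_residues_min,
       exclusive_residues = exclusive_residues)
}

# resolve one subject id against the mapping table: exact match first,
# then prefix match; first matching row wins. NA when unmapped.
map_subjects <- function(subject_id, mapping) {
  idx <- rep(NA_integer_, length(subject_id))
  for (j in seq_along(subject_id)) {
    hit <- which(mapping$subject_pattern == subject_id[j])
    if (!length(hit)) {
      hit <- which(startsWith(subject_id[j], mapping$subject_pattern))
    }
    if (length(hit)) idx[j] <- hit[1]
  }
  idx
}

#' Protein-evidence concordance label (PE / DA / NE)
#'
#' Labels a consensus by whether its TE-protein hits support the assigned
#' classification: `PE` when at least one mapped hit is concordant and none
#' is discordant, `DA` when any mapped hit is discordant (conflict is the
#' signal this label carries), `NE` when there are no hits or none maps to
#' an informative classification (which includes putative non-autonomous
#' TEs). Concordance is evaluated at the high classification level, refined
#' by the sub-level only when both sides define one; an `Unknown`
#' classification is compatible with any evidence.
#'
#' @param class_high,class_sub Classification of the consensus (`class_sub`
#'   may be NA).
#' @param te_hits Hit tibble of threshold-filtered TE hits (`TE_HMM` /
#'   `TE_PEP`) for this consensus.
#' @param mapping Domain-to-classification tibble with columns
#'   `subject_pattern`, `class_high`, `class_sub`; matched against
#'   `subject_id` exactly or as a prefix. If `NULL`, the hits'
#'   `subject_class_high`/`subject_class_sub` columns are used directly.
#' @return `"PE"`, `"DA"`, or `"NE"`.
#' @export
label_evidence <- function(class_high, class_sub, te_hits, mapping = NULL) {
  if (is.null(te_hits) || nrow(te_hits) == 0) return("NE")
  if (!is.null(mapping)) {
    idx <- map_subjects(te_hits$subject_id, mapping)
    unmapped <- unique(te_hits$subject_id[is.na(idx)])
    if (length(unmapped)) {
      warning(sprintf("subject(s) not in mapping table, treated as unmapped: %s",
                      paste(unmapped, collapse = ", ")), call. = FALSE)
    }
    hit_high <- mapping$class_high[idx]
    hit_sub <- mapping$class_sub[idx]
  } else {
    hit_high <- te_hits$subject_class_high
    hit_sub <- te_hits$subject_class_sub
  }
  informative <- !is.na(hit_high) & nzchar(hit_high) & hit_high != "Unknown"
  hit_high <- hit_high[informative]
  hit_sub <- hit_sub[informative]
  if (!length(hit_high)) return("NE")
  if (is.na(class_high) || class_high == "Unknown") return("PE")
  high_mismatch <- hit_high != class_high
  sub_defined <- !is.na(class_sub) & nzchar(class_sub) &
    !is.na(hit_sub) & nzchar(hit_sub)
  sub_mismatch <- !high_mismatch & sub_defined & hit_sub != class_sub
  if (any(high_mismatch | sub_mismatch)) "DA" else "PE"
}

#' Sequence quality filter
#'
#' A consensus is removed as poor quality when it is shorter than
#' `min_length_nt` (strict) or its N fraction is at least `n_fraction_max`
#' (inclusive).
#'
#' @param sequence Character vector of consensus sequences.
#' @param th A [curation_thresholds()] object.
#' @return A tibble with logical `removed` and a comma-joined `reasons`
#'   column using codes `SHORT` and `N_RICH`.
#' @export
quality_filter <- function(sequence, th = curation_thresholds()) {
  short <- nchar(sequence) < th$min_length_nt
  n_rich <- n_fraction(sequence) >= th$n_fraction_max
  reasons <- mapply(function(s, n) {
    paste(c(if (s) "SHORT", if (n) "N_RICH"), collapse = ",")
  }, short, n_rich)
  tibble(removed = short | n_rich, reasons = unname(reasons))
}

#' Assembly N50 from contig lengths
#'
#' The N50 is the smallest contig length such that contigs at least that
#' long sum to at least half the assembly size.
#'
#' @param contig_lengths Positive integer vector of contig lengths.
#' @return The N50 in bp.
#' @examples
#' contig_n50(c(100, 200, 300, 400) * 1000)
#' @export
contig_n50 <- function(contig_lengths) {
  stopifnot(length(contig_lengths) > 0, all(contig_lengths > 0))
  lens <- sort(as.numeric(contig_lengths), decreasing = TRUE)
  lens[which(cumsum(lens) >= sum(lens) / 2)[1]]
}

#' Flag consensus sequences from low-quality genomes
#'
#' A genome is low quality when its N50 is below `n50_min_bp` *and* its
#' BUSCO completeness is below `busco_complete_min_pct` (conjunction).
#'
#' @param n50_bp Numeric vector of assembly N50 values.
#' @param busco_complete_pct Numeric vector of BUSCO complete percentages;
#'   NA is an error (the flag cannot be evaluated).
#' @param th A [curation_thresholds()] object.
#' @return Logical vector.
#' @export
flag_lq_genome <- function(n50_bp, busco_complete_pct,
                           th = curation_thresholds()) {
  if (anyNA(busco_complete_pct)) {
    stop("missing BUSCO completeness value; cannot evaluate LQGenome flag",
         call. = FALSE)
  }
  if (anyNA(n50_bp)) {
    stop("missing N50 value; cannot evaluate LQGenome flag", call. = FALSE)
  }
  n50_bp < th$n50_min_bp & busco_complete_pct < th$busco_complete_min_pct
}

#' Read genome assembly metadata
#'
#' Expects a TSV with columns `assembly_id`, `species` (`"Genus epithet"`),
#' `n50_bp`, `busco_complete_pct`.
#'
#' @param path Path to the TSV.
#' @return A tibble.
#' @export
read_genome_metadata <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    assembly_id = "c", species = "c",
                    n50_bp = "d", busco_complete_pct = "d"))
}

#' Read a domain-to-classification mapping table
#'
#' Expects a TSV with columns `subject_pattern`, `class_high`, `class_sub`
#' (empty `class_sub` allowed; empty `class_high` marks an uninformative
#' domain).
#'
#' @param path Path to the TSV.
#' @return A tibble.
#' @export
read_domain_mapping <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(.default = "c"))
}

# coverage interval sets per category for one consensus's hits:
# nested-hit resolution per category, then merging with the gap tolerance
hit_coverage <- function(hits, gap_max_nt, per_subject = FALSE) {
  out <- list()
  for (cat in intersect(hit_categories, unique(hits$category))) {
    h <- resolve_nested(hits[hits$category == cat, , drop = FALSE])
    if (per_subject && cat == "HOST_REFSEQ") {
      out[[cat]] <- lapply(split(h, h$subject_id), merge_hits,
                           gap_max_nt = gap_max_nt)
    } else {
      out[[cat]] <- merge_hits(h, gap_max_nt = gap_max_nt)
    }
  }
  out
}

#' Curate a consensus library
#'
#' Runs the per-record decision pipeline in library-construction order: host-gene
#' designation first (records failing both rules count as host genes), then
#' sequence quality filtering, then evidence labels and genome-quality
#' flags on the retained records. Records with no hits at all are retained
#' as putative non-autonomous TEs with evidence `NE`.
#'
#' @param library A library tibble (see [read_te_library()]); the
#'   `source_genome` column links records to `genome_meta`.
#' @param hits A hit tibble, already threshold-filtered with
#'   [filter_hits()]; nt spans are projected here if missing. Every
#'   `consensus_id` must exist in `library`.
#' @param genome_meta Optional genome metadata tibble (see
#'   [read_genome_metadata()]); when `NULL`, no record is flagged
#'   `LQGenome`.
#' @param mapping Optional domain-to-classification mapping for
#'   [label_evidence()].
#' @param th A [curation_thresholds()] object.
#' @param gap_max_nt Gap tolerance for [merge_hits()].
#' @param exclusive_mode `"union"` (default) counts RefSeq-exclusive
#'   residues on the union of all RefSeq subjects; `"per_subject"` requires
#'   a single RefSeq subject to contribute the exclusive residues and takes
#'   the maximum over subjects.
#' @return A list with `library` (the retained records, evidence and
#'   `lq_genome` filled) and `verdicts` (one row per input record:
#'   `consensus_id`, `host_gene`, `non_autonomous`, `evidence`,
#'   `removed_quality`, `lq_genome`, `exclusive_refseq_residues`,
#'   `reasons`).
#' @export
curate_library <- function(library, hits = NULL, genome_meta = NULL,
                           mapping = NULL, th = curation_thresholds(),
                           gap_max_nt = 30L,
                           exclusive_mode = c("union", "per_subject")) {
  exclusive_mode <- match.arg(exclusive_mode)
  if (is.null(hits)) hits <- empty_hits()
  orphans <- setdiff(unique(hits$consensus_id), library$record_id)
  if (length(orphans)) {
    stop(sprintf("hits reference consensus id(s) absent from the library: %s",
                 paste(orphans, collapse = ", ")), call. = FALSE)
  }
  if (nrow(hits) > 0 && anyNA(hits$nt_start)) {
    hits <- project_hits(hits, library)
  }
  hits_by_id <- split(hits, factor(hits$consensus_id,
                                   levels = library$record_id))

  n <- nrow(library)
  host_gene <- logical(n)
  exclusive <- integer(n)
  evidence <- character(n)
  non_autonomous <- logical(n)
  reasons <- vector("list", n)

  for (i in seq_len(n)) {
    h <- hits_by_id[[library$record_id[i]]]
    cov <- hit_coverage(h, gap_max_nt,
                        per_subject = exclusive_mode == "per_subject")
    te_cov <- Reduce(interval_union,
                     cov[intersect(c("TE_HMM", "TE_PEP"), names(cov))],
                     tibble(start = integer(), end = integer()))
    refseq <- cov[["HOST_REFSEQ"]]
    if (exclusive_mode == "per_subject" && !is.null(refseq)) {
      per <- lapply(refseq, classify_host_gene, te_cov = te_cov, th = th)
      best <- which.max(vapply(per, `[[`, integer(1), "exclusive_residues"))
      host_gene[i] <- any(vapply(per, `[[`, logical(1), "host_gene"))
      exclusive[i] <- per[[best]]$exclusive_residues
    } else {
      if (is.null(refseq)) refseq <- tibble(start = integer(), end = integer())
      verdict <- classify_host_gene(refseq, te_cov, th)
      host_gene[i] <- verdict$host_gene
      exclusive[i] <- verdict$exclusive_residues
    }
    te_hits <- h[h$category %in% c("TE_HMM", "TE_PEP"), , drop = FALSE]
    evidence[i] <- label_evidence(library$class_high[i],
                                  library$class_sub[i], te_hits, mapping)
    non_autonomous[i] <- nrow(h) == 0
    r <- character(0)
    if (host_gene[i]) {
      r <- c(r, if (interval_width(te_cov) == 0L) "HOST_NO_TE"
              else "HOST_EXCLUSIVE")
    }
    if (non_autonomous[i]) r <- c(r, "NON_AUTONOMOUS")
    reasons[[i]] <- r
  }

  qual <- quality_filter(library$sequence, th)
  removed_quality <- qual$removed & !host_gene  # host-gene stage runs first
  reasons <- mapply(function(r, q, counted) {
    paste(c(r, if (counted && nzchar(q)) strsplit(q, ",")[[1]]),
          collapse = ",")
  }, reasons, qual$reasons, removed_quality)

  lq <- rep(FALSE, n)
  if (!is.null(genome_meta) && !all(is.na(library$source_genome))) {
    m <- match(library$source_genome, genome_meta$assembly_id)
    known <- !is.na(library$source_genome)
    if (any(known & is.na(m))) {
      warning(sprintf("no genome metadata for assembly id(s): %s",
                      paste(unique(library$source_genome[known & is.na(m)]),
                            collapse = ", ")), call. = FALSE)
    }
    ok <- known & !is.na(m)
    if (any(ok)) {
      lq[ok] <- flag_lq_genome(genome_meta$n50_bp[m[ok]],
                               genome_meta$busco_complete_pct[m[ok]], th)
    }
  }

  verdicts <- tibble(
    consensus_id = library$record_id,
    host_gene = host_gene,
    non_autonomous = non_autonomous,
    evidence = evidence,
    removed_quality = removed_quality,
    lq_genome = lq,
    exclusive_refseq_residues = exclusive,
    reasons = unname(reasons)
  )

  retained <- library[!host_gene & !removed_quality, , drop = FALSE]
  retained$evidence <- evidence[!host_gene & !removed_quality]
  retained$lq_genome <- lq[!host_gene & !removed_quality]
  list(library = retained, verdicts = verdicts)
}

#' Write a curation verdicts table as TSV
#'
#' @param verdicts The `verdicts` tibble of [curate_library()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_verdicts_tsv <- function(verdicts, path) {
  readr::write_tsv(verdicts, path, progress = FALSE)
  invisible(path)
}
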