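# Deterministic synthetic fixtures with independently computed ground
# truth. The truth tables are produced by per-position brute force over the
# planted hit geometry (re-stating thresholds and the frame projection
# arithmetic), never by the curation code under test.

# run code under a seed, restoring the caller's RNG state afterwards
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_dna <- function(sequence, rate, protect_ends = 0L) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  idx <- which(stats::runif(n) < rate)
  if (protect_ends > 0) {
    idx <- idx[idx > protect_ends & idx <= n - protect_ends]
  }
  for (i in idx) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
  }
  paste(chars, collapse = "")
}

#' Synthetic fixture specification
#'
#' Describes the composition of a synthetic consensus library with planted
#' curation outcomes. The defaults plant: three clean TEs covering the
#' three evidence labels (a concordant `PE` case, a discordant `DA` case,
#' and an unclassified non-autonomous `NE` case), two branch-(i) host genes
#' (RefSeq hits only), two branch-(ii) host genes (149 RefSeq-exclusive
#' residues), one borderline record at 89 exclusive residues (retained),
#' two too-short records (119 and 60 nt), and one N-rich record (5% N).
#'
#' @param seed Integer seed; all fixture randomness flows from it.
#' @param n_clean_te,n_host_gene_case_i,n_host_gene_case_ii,n_borderline,n_short,n_n_rich
#'   Record counts per planted category.
#' @param n_families,copies_per_family,substitution_rate Parameters for the
#'   companion family set (see [make_family_set()]).
#' @param genome_length,n_features Geometry of the planted annotation
#'   comparison pair.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_clean_te = 3L, n_host_gene_case_i = 2L,
                         n_host_gene_case_ii = 2L, n_borderline = 1L,
                         n_short = 2L, n_n_rich = 1L, n_families = 3L,
                         copies_per_family = 4L, substitution_rate = 0.05,
                         genome_length = 100000L, n_features = 12L) {
  stopifnot(seed == as.integer(seed), substitution_rate >= 0,
            substitution_rate < 1)
  structure(as.list(environment()), class = "fixture_spec")
}

# genomes used by the fixture; CN_LQ1 is the planted low-quality assembly
fixture_genomes <- function() {
  tibble(
    assembly_id = c("ZT001", "MO001", "CN_LQ1"),
    species = c("Zymoseptoria tritici", "Magnaporthe oryzae",
                "Cryptococcus neoformans"),
    n50_bp = c(2e6, 1e5, 4e4),
    busco_complete_pct = c(98, 95, 85)
  )
}

fixture_mapping <- function() {
  tibble(
    subject_pattern = c("GypsyPol", "CopiaPol", "hATTpase", "PF_Gypsy",
                        "UncharDom"),
    class_high = c("LTR", "LTR", "DNA", "LTR", ""),
    class_sub = c("Gypsy", "Copia", "hAT", "Gypsy", "")
  )
}

# independent projection arithmetic (duplicated on purpose; see file header)
.truth_project <- function(frame, rs, re, L) {
  if (frame <= 3) {
    c(3 * rs + frame - 1, 3 * re + frame - 1)
  } else {
    sp <- 3 * rs + frame - 4
    ep <- 3 * re + frame - 4
    c(L - ep, L - sp)
  }
}

# per-position coverage with gap closing (independent brute force)
.truth_cover <- function(spans, L, gap = 30L) {
  covered <- logical(L)
  for (s in spans) covered[(s[1] + 1):s[2]] <- TRUE
  if (!any(covered)) return(covered)
  runs <- rle(covered)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  for (k in seq_along(runs$values)) {
    if (!runs$values[k] && k > 1 && k < length(runs$values) &&
        runs$lengths[k] <= gap) {
      covered[starts[k]:ends[k]] <- TRUE
    }
  }
  covered
}

#' Generate the synthetic curation fixture
#'
#' Writes a consensus library FASTA, protein hit tables (12-column tabular
#' BLAST for RefSeq and TE-peptide hits, a HMMER domain table for
#' TE-profile hits), genome metadata, a domain-classification mapping, a
#' planted annotation comparison pair (BED + GFF3), and an
#' `expected_verdicts.tsv` ground-truth table computed by an independent
#' per-position brute-force routine at generation time. Output is
#' byte-identical for a given spec.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the file `paths`, the ground-truth
#'   `truth` tibble, and the planted `comparison_truth`.
#' @export
make_fixture <- function(spec = fixture_spec(), dir = tempfile("fixture")) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  with_seed(spec$seed, {
    recs <- list()   # record_id, sequence, class_high, class_sub, genome
    hits <- list()   # consensus_id, frame, rs, re, subject, category, evalue, bitscore
    genomes <- fixture_genomes()
    add_rec <- function(id, seq, high, sub, genome) {
      recs[[length(recs) + 1]] <<- tibble(
        record_id = id, sequence = seq, class_high = high,
        class_sub = sub, genome = genome)
    }
    add_hit <- function(id, frame, rs, re, subject, category,
                        evalue = 1e-10, bitscore = 120) {
      hits[[length(hits) + 1]] <<- tibble(
        consensus_id = id, frame = frame, rs = rs, re = re,
        subject = subject, category = category, evalue = evalue,
        bitscore = bitscore)
    }

    # clean TEs cycling PE / DA / NE designs
    for (i in seq_len(spec$n_clean_te)) {
      id <- sprintf("clean%d", i)
      L <- 3 * sample(300:500, 1)
      kind <- (i - 1) %% 3 + 1
      if (kind == 1) {          # PE: concordant peptide + profile evidence
        add_rec(id, random_dna(L), "LTR", "Gypsy", "ZT001")
        add_hit(id, 1, 10, 210, "GypsyPol_1", "TE_PEP")
        add_hit(id, 5, 5, 105, "PF_Gypsy_RT", "TE_HMM", bitscore = 80)
      } else if (kind == 2) {   # DA: peptide evidence contradicts the class
        add_rec(id, random_dna(L), "DNA", "hAT", "MO001")
        add_hit(id, 2, 20, 140, "CopiaPol_2", "TE_PEP")
      } else {                  # NE: unclassified, no hits (non-autonomous)
        add_rec(id, random_dna(L), "Unknown", NA_character_, "CN_LQ1")
      }
    }
    # branch (i) host genes: RefSeq hits only; first one also gets a decoy
    # TE profile hit below the bit-score threshold
    for (i in seq_len(spec$n_host_gene_case_i)) {
      id <- sprintf("hosti%d", i)
      L <- 1200
      add_rec(id, random_dna(L), "Unknown", NA_character_, "ZT001")
      add_hit(id, 1, 10, 310, sprintf("XP_%06d.1", i), "HOST_REFSEQ")
      if (i == 1) {
        add_hit(id, 1, 50, 150, "PF_Gypsy_RT", "TE_HMM",
                evalue = 5e-4, bitscore = 49)
      }
    }
    # branch (ii) host genes: RefSeq [0,600), TE [447,780) -> 149 exclusive
    for (i in seq_len(spec$n_host_gene_case_ii)) {
      id <- sprintf("hostii%d", i)
      L <- 900
      add_rec(id, random_dna(L), "LINE", NA_character_, "MO001")
      add_hit(id, 1, 0, 200, sprintf("XP_%06d.1", 100 + i), "HOST_REFSEQ")
      add_hit(id, 1, 149, 260, "GypsyPol_1", "TE_PEP")
    }
    # borderline: RefSeq residues [0,150), TE residues [89,150)
    # -> 267 exclusive nt = 89 residues: retained
    for (i in seq_len(spec$n_borderline)) {
      id <- sprintf("border%d", i)
      L <- 600
      add_rec(id, random_dna(L), "LTR", "Gypsy", "ZT001")
      add_hit(id, 1, 0, 150, sprintf("XP_%06d.1", 200 + i), "HOST_REFSEQ")
      add_hit(id, 1, 89, 150, "GypsyPol_1", "TE_PEP")
    }
    # too short (119 nt at the boundary, then shorter)
    short_lengths <- c(119L, 60L, 100L, 90L, 80L)
    for (i in seq_len(spec$n_short)) {
      add_rec(sprintf("short%d", i), random_dna(short_lengths[i]),
              "Unknown", NA_character_, "ZT001")
    }
    # N-rich: 200 nt with exactly 10 N (5%, inclusive boundary)
    for (i in seq_len(spec$n_n_rich)) {
      seq <- strsplit(random_dna(200L), "")[[1]]
      seq[sample(200L, 10L)] <- "N"
      add_rec(sprintf("nrich%d", i), paste(seq, collapse = ""),
              "Unknown", NA_character_, "MO001")
    }

    recs <- bind_rows(recs)
    hits <- if (length(hits)) bind_rows(hits) else
      tibble(consensus_id = character(), frame = integer(), rs = integer(),
             re = integer(), subject = character(), category = character(),
             evalue = numeric(), bitscore = numeric())

    # ---- ground truth by per-position brute force --------------------
    mapping <- fixture_mapping()
    truth <- lapply(seq_len(nrow(recs)), function(i) {
      id <- recs$record_id[i]
      L <- nchar(recs$sequence[i])
      h <- hits[hits$consensus_id == id, , drop = FALSE]
      pass <- (h$category == "HOST_REFSEQ" & h$evalue <= 1e-3) |
        (h$category == "TE_HMM" & h$evalue <= 1e-3 & h$bitscore >= 50) |
        (h$category == "TE_PEP" & h$evalue <= 1e-3)
      h <- h[pass, , drop = FALSE]
      spans <- lapply(seq_len(nrow(h)), function(j) {
        .truth_project(h$frame[j], h$rs[j], h$re[j], L)
      })
      ref <- .truth_cover(spans[h$category == "HOST_REFSEQ"], L)
      te <- .truth_cover(spans[h$category != "HOST_REFSEQ"], L)
      exclusive_res <- sum(ref & !te) %/% 3
      host <- (any(ref) && !any(te)) ||
        (any(ref) && any(te) && exclusive_res >= 90)
      n_frac <- sum(strsplit(recs$sequence[i], "")[[1]] == "N") / L
      removed_q <- !host && (L < 120 || n_frac >= 0.05)
      te_h <- h[h$category != "HOST_REFSEQ", , drop = FALSE]
      midx <- vapply(te_h$subject, function(s) {
        w <- which(startsWith(s, mapping$subject_pattern))
        if (length(w)) w[1] else NA_integer_
      }, integer(1))
      m_high <- mapping$class_high[midx]
      m_sub <- mapping$class_sub[midx]
      informative <- !is.na(m_high) & nzchar(m_high)
      ev <- if (!any(informative)) "NE"
        else if (recs$class_high[i] == "Unknown") "PE"
        else {
          disc <- (m_high[informative] != recs$class_high[i]) |
            (!is.na(recs$class_sub[i]) & nzchar(m_sub[informative]) &
               m_high[informative] == recs$class_high[i] &
               m_sub[informative] != recs$class_sub[i])
          if (any(disc)) "DA" else "PE"
        }
      g <- genomes[genomes$assembly_id == recs$genome[i], ]
      tibble(
        record_id = id, host_gene = host, removed_quality = removed_q,
        retained = !host && !removed_q, evidence = ev,
        non_autonomous = nrow(h) == 0,
        lq_genome = g$n50_bp < 5e4 && g$busco_complete_pct < 90,
        exclusive_refseq_residues = as.integer(exclusive_res)
      )
    })
    truth <- bind_rows(truth)

    # ---- write files -------------------------------------------------
    paths <- list(
      library = file.path(dir, "library.fa"),
      refseq_hits = file.path(dir, "refseq_hits.tsv"),
      te_pep_hits = file.path(dir, "te_pep_hits.tsv"),
      te_hmm_hits = file.path(dir, "te_hmm_hits.domtbl"),
      genomes = file.path(dir, "genomes.tsv"),
      mapping = file.path(dir, "mapping.tsv"),
      annotations_a = file.path(dir, "annotations_a.bed"),
      annotations_b = file.path(dir, "annotations_b.gff3"),
      expected_verdicts = file.path(dir, "expected_verdicts.tsv")
    )

    header <- ifelse(
      recs$class_high == "Unknown" & is.na(recs$class_sub),
      paste0(recs$record_id, " ", recs$genome),
      paste0(recs$record_id, "#", recs$class_high,
             ifelse(is.na(recs$class_sub), "", paste0("/", recs$class_sub)),
             " ", recs$genome))
    writeLines(unlist(lapply(seq_len(nrow(recs)), function(i) {
      c(paste0(">", header[i]),
        substring(recs$sequence[i],
                  seq(1, nchar(recs$sequence[i]), 60),
                  pmin(seq(1, nchar(recs$sequence[i]), 60) + 59,
                       nchar(recs$sequence[i]))))
    })), paths$library)

    blast_lines <- function(h) {
      vapply(seq_len(nrow(h)), function(j) {
        len <- h$re[j] - h$rs[j]
        paste(sprintf("%s_%d", h$consensus_id[j], h$frame[j]), h$subject[j],
              "97.5", len, "2", "0", h$rs[j] + 1, h$re[j], "1", len,
              format(h$evalue[j], scientific = TRUE), h$bitscore[j],
              sep = "\t")
      }, character(1))
    }
    writeLines(blast_lines(hits[hits$category == "HOST_REFSEQ", ]),
               paths$refseq_hits)
    writeLines(blast_lines(hits[hits$category == "TE_PEP", ]),
               paths$te_pep_hits)

    hmm <- hits[hits$category == "TE_HMM", , drop = FALSE]
    domtbl <- c(
      "# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target",
      "#------------------- ---------- ----- -------------------- ---------- ----- --------- ------ ----- --- --- --------- --------- ------ ----- ----- ----- ----- ----- ----- ----- ---- ---------------------",
      vapply(seq_len(nrow(hmm)), function(j) {
        len <- hmm$re[j] - hmm$rs[j]
        paste(hmm$subject[j], "-", len,
              sprintf("%s_%d", hmm$consensus_id[j], hmm$frame[j]), "-", 500,
              format(hmm$evalue[j], scientific = TRUE), hmm$bitscore[j], "0.1",
              1, 1, format(hmm$evalue[j], scientific = TRUE),
              format(hmm$evalue[j], scientific = TRUE), hmm$bitscore[j], "0.1",
              1, len, hmm$rs[j] + 1, hmm$re[j], hmm$rs[j] + 1, hmm$re[j],
              "0.95", "-", sep = " ")
      }, character(1)))
    writeLines(domtbl, paths$te_hmm_hits)

    readr::write_tsv(genomes, paths$genomes, progress = FALSE)
    readr::write_tsv(mapping, paths$mapping, progress = FALSE)
    readr::write_tsv(truth, paths$expected_verdicts, progress = FALSE)

    cmp <- make_annotation_pair(genome_length = spec$genome_length,
                                n_features = spec$n_features,
                                bed_path = paths$annotations_a,
                                gff_path = paths$annotations_b)

    invisible(list(paths = paths, truth = truth,
                   comparison_truth = cmp$truth))
  })
}

#' Generate a planted pair of TE annotation sets
#'
#' Lays out non-overlapping loci on one contig and assigns each to method
#' A only, method B only, or both (with independently jittered extents for
#' the shared loci, so per-method widths differ). The ground-truth shared
#' and unique base-pair counts are computed by per-position brute force
#' over boolean arrays.
#'
#' @param genome_length Contig length in bp.
#' @param n_features Number of planted loci.
#' @param bed_path,gff_path Output paths for method A (BED) and method B
#'   (GFF3).
#' @return A list with `truth` (tibble: `category`, `bp`) and the two
#'   paths. Uses the current RNG state; seed it (or call via
#'   [make_fixture()]) for reproducibility.
#' @export
make_annotation_pair <- function(genome_length = 100000L, n_features = 12L,
                                 bed_path, gff_path) {
  classes <- c("LTR/Gypsy", "DNA/hAT", "LINE/L1", "Unknown")
  slot <- genome_length %/% n_features
  a <- list(); b <- list()
  for (k in seq_len(n_features)) {
    lo <- (k - 1) * slot
    len <- sample(200:min(800, slot %/% 2), 1)
    s <- lo + sample(0:(slot - len - 50), 1)
    cls <- classes[(k - 1) %% length(classes) + 1]
    kind <- k %% 3
    if (kind == 0) {          # A only
      a[[length(a) + 1]] <- tibble(start = s, end = s + len, class = cls)
    } else if (kind == 1) {   # B only
      b[[length(b) + 1]] <- tibble(start = s, end = s + len, class = cls)
    } else {                  # shared locus, jittered extents per method
      ja <- sample(0:40, 2); jb <- sample(0:40, 2)
      a[[length(a) + 1]] <- tibble(start = s - ja[1], end = s + len + ja[2],
                                   class = cls)
      b[[length(b) + 1]] <- tibble(start = s - jb[1], end = s + len + jb[2],
                                   class = cls)
    }
  }
  a <- bind_rows(a); b <- bind_rows(b)
  a$start <- pmax(a$start, 0L); b$start <- pmax(b$start, 0L)

  cov_a <- logical(genome_length); cov_b <- logical(genome_length)
  for (i in seq_len(nrow(a))) cov_a[(a$start[i] + 1):a$end[i]] <- TRUE
  for (i in seq_len(nrow(b))) cov_b[(b$start[i] + 1):b$end[i]] <- TRUE
  truth <- tibble(
    category = c("shared", "unique_A", "unique_B"),
    bp = c(sum(cov_a & cov_b), sum(cov_a & !cov_b), sum(!cov_a & cov_b))
  )

  writeLines(sprintf("contig1\t%d\t%d\t%s", a$start, a$end, a$class),
             bed_path)
  gff <- c("##gff-version 3",
           sprintf(
             "contig1\tfixture\tdispersed_repeat\t%d\t%d\t.\t+\t.\tID=rep%d;Name=%s",
             b$start + 1, b$end, seq_len(nrow(b)), b$class))
  writeLines(gff, gff_path)
  list(truth = truth, bed_path = bed_path, gff_path = gff_path)
}

#' Generate planted TE families for clustering tests
#'
#' Each family descends from one random ancestor (300-2000 nt) by
#' independent per-position substitution at `substitution_rate`; half of
#' the copies are reverse-complemented to exercise strand handling. The
#' truth table records the planted family of every sequence.
#'
#' @param n_families,copies Number of families and copies per family.
#' @param substitution_rate Per-position substitution probability.
#' @param seed Integer seed.
#' @param length_range Ancestor length range in nt.
#' @return A list with `library` (a library tibble) and `truth`
#'   (`record_id`, `family`).
#' @export
make_family_set <- function(n_families = 3L, copies = 4L,
                            substitution_rate = 0.05, seed = 1L,
                            length_range = c(300L, 2000L)) {
  with_seed(seed, {
    recs <- list(); fam <- list()
    for (f in seq_len(n_families)) {
      L <- sample(length_range[1]:length_range[2], 1)
      anc <- random_dna(L)
      for (c_i in seq_len(copies)) {
        seq <- mutate_dna(anc, substitution_rate)
        if (c_i %% 2 == 0) seq <- revcomp(seq)
        id <- sprintf("fam%d_copy%d", f, c_i)
        recs[[length(recs) + 1]] <- tibble(record_id = id, sequence = seq)
        fam[[length(fam) + 1]] <- tibble(record_id = id, family = f)
      }
    }
    lib <- bind_rows(recs)
    lib$class_high <- "Unknown"
    lib$class_sub <- NA_character_
    lib$genus <- "Zymoseptoria"
    lib$epithet <- "tritici"
    lib$evidence <- NA_character_
    lib$lq_genome <- FALSE
    lib$source_genome <- "ZT001"
    list(library = lib, truth = bind_rows(fam))
  })
}
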