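empty_iv <- function() tibble::tibble(start = integer(), end = integer())

test_that("host-gene rule follows both branches and the residue floor", {
  # branch (i): RefSeq evidence only
  v <- classify_host_gene(interval_set(0, 600), empty_iv())
  expect_true(v$host_gene)
  expect_equal(v$exclusive_residues, 200L)
  # branch (ii) below threshold
  v <- classify_host_gene(interval_set(0, 300), interval_set(57, 300))
  expect_false(v$host_gene)
  expect_equal(v$exclusive_residues, 19L)
  # branch (ii) above threshold
  v <- classify_host_gene(interval_set(0, 600), interval_set(447, 780))
  expect_true(v$host_gene)
  expect_equal(v$exclusive_residues, 149L)
  # no RefSeq evidence at all
  v <- classify_host_gene(empty_iv(), interval_set(0, 100))
  expect_false(v$host_gene)
  expect_equal(v$exclusive_residues, 0L)
})

test_that("host-gene boundary behaviour at 89/90/91 exclusive residues", {
  for (res in c(89L, 90L, 91L)) {
    v <- classify_host_gene(interval_set(0, 3L * res + 300L),
                            interval_set(3L * res, 3L * res + 300L))
    expect_equal(v$exclusive_residues, res)
    expect_equal(v$host_gene, res >= 90L)
  }
})

test_that("exclusive residues equal the per-position oracle (property)", {
  withr::with_seed(99, {
    for (rep in 1:200) {
      L <- 900L
      ref <- random_intervals(sample(1:8, 1), L)
      te <- random_intervals(sample(0:8, 1), L)
      v <- classify_host_gene(merge_intervals(ref), merge_intervals(te))
      nt <- oracle_exclusive_nt(ref$start, ref$end, te$start, te$end, L)
      expect_equal(v$exclusive_residues, nt %/% 3L)
    }
  })
})

test_that("host-gene call is monotone in added coverage (property)", {
  withr::with_seed(7, {
    for (rep in 1:50) {
      L <- 600L
      ref <- merge_intervals(random_intervals(sample(1:5, 1), L))
      te <- merge_intervals(random_intervals(1, L))
      extra_te <- merge_intervals(dplyr::bind_rows(te, random_intervals(2, L)))
      base <- classify_host_gene(ref, te)
      more_te <- classify_host_gene(ref, extra_te)
      # adding TE coverage can never create a host-gene call
      if (!base$host_gene) expect_false(more_te$host_gene)
      # adding RefSeq coverage can never lose one (branch ii)
      extra_ref <- merge_intervals(dplyr::bind_rows(ref, random_intervals(2, L)))
      if (base$host_gene) {
        expect_true(classify_host_gene(extra_ref, te)$host_gene)
      }
    }
  })
})

test_that("evidence labels encode concordance, conflict, and absence", {
  mapping <- tibble::tibble(
    subject_pattern = c("GypsyPol", "LTRdom", "CopiaPol", "weak"),
    class_high = c("LTR", "LTR", "LTR", ""),
    class_sub = c("Gypsy", NA, "Copia", NA))
  hits2 <- dplyr::bind_rows(make_hit(subject_id = "GypsyPol_1"),
                            make_hit(subject_id = "LTRdom_2"))
  expect_equal(label_evidence("LTR", "Gypsy", hits2, mapping), "PE")
  expect_equal(label_evidence("DNA", "hAT",
                              make_hit(subject_id = "CopiaPol_9"), mapping), "DA")
  expect_equal(label_evidence("Unknown", NA, NULL, mapping), "NE")
  expect_equal(label_evidence("Unknown", NA, make_hit(0)[0, ], mapping), "NE")
  # uninformative mapping rows do not count as evidence
  expect_equal(label_evidence("LTR", "Gypsy",
                              make_hit(subject_id = "weak_1"), mapping), "NE")
  # sub-level conflict within the same high level is a conflict
  expect_equal(label_evidence("LTR", "Gypsy",
                              make_hit(subject_id = "CopiaPol_1"), mapping), "DA")
  # any discordant hit forces DA even alongside concordant hits
  both <- dplyr::bind_rows(make_hit(subject_id = "GypsyPol_1"),
                           make_hit(subject_id = "CopiaPol_1"))
  expect_equal(label_evidence("LTR", "Gypsy", both, mapping), "DA")
  # unmapped subjects warn and are ignored
  expect_warning(
    out <- label_evidence("LTR", "Gypsy",
                          make_hit(subject_id = "mystery"), mapping),
    "unmapped")
  expect_equal(out, "NE")
})

test_that("evidence is NE exactly when no hit maps to a classification (property)", {
  mapping <- tibble::tibble(subject_pattern = c("dom", "null"),
                            class_high = c("LTR", ""), class_sub = c(NA, NA))
  withr::with_seed(13, {
    for (rep in 1:50) {
      n <- sample(0:4, 1)
      hits <- if (n == 0) make_hit()[0, ] else dplyr::bind_rows(
        lapply(seq_len(n), function(i) {
          make_hit(subject_id = sample(c("dom_1", "null_2"), 1))
        }))
      lab <- suppressWarnings(label_evidence("LTR", NA, hits, mapping))
      mapped <- n > 0 && any(startsWith(hits$subject_id, "dom"))
      expect_equal(lab == "NE", !mapped)
    }
  })
})

test_that("quality filter applies strict length and inclusive N thresholds", {
  q <- quality_filter(c(strrep("A", 119), strrep("A", 120),
                        paste0(strrep("A", 190), strrep("N", 10)),
                        paste0(strrep("A", 191), strrep("N", 9)),
                        paste0(strrep("N", 10), strrep("A", 90))))
  expect_equal(q$removed, c(TRUE, FALSE, TRUE, FALSE, TRUE))
  expect_equal(q$reasons, c("SHORT", "", "N_RICH", "", "SHORT,N_RICH"))
})

test_that("N50 and the LQGenome conjunction behave as specified", {
  expect_equal(contig_n50(c(100, 200, 300, 400) * 1000), 300000)
  expect_equal(contig_n50(5), 5)
  th <- curation_thresholds()
  expect_true(flag_lq_genome(40000, 85, th))
  expect_false(flag_lq_genome(40000, 95, th))   # conjunction: one clause fails
  expect_false(flag_lq_genome(60000, 85, th))
  expect_false(flag_lq_genome(contig_n50(c(100, 200, 300, 400) * 1000), 10, th))
  expect_error(flag_lq_genome(40000, NA, th), "BUSCO")
})

test_that("library curation applies stages in order with full accounting", {
  fx <- make_fixture(fixture_spec(seed = 3), dir = withr::local_tempdir())
  lib <- read_te_library(fx$paths$library)
  hits <- filter_hits(dplyr::bind_rows(
    read_blast_hits(fx$paths$refseq_hits, "HOST_REFSEQ"),
    read_blast_hits(fx$paths$te_pep_hits, "TE_PEP"),
    read_domtbl_hits(fx$paths$te_hmm_hits)))
  cur <- curate_library(lib, hits,
                        genome_meta = read_genome_metadata(fx$paths$genomes),
                        mapping = read_domain_mapping(fx$paths$mapping))
  v <- dplyr::arrange(cur$verdicts, consensus_id)
  t <- dplyr::arrange(fx$truth, record_id)
  expect_equal(v$host_gene, t$host_gene)
  expect_equal(v$removed_quality, t$removed_quality)
  expect_equal(v$evidence, t$evidence)
  expect_equal(v$non_autonomous, t$non_autonomous)
  expect_equal(v$lq_genome, t$lq_genome)
  expect_equal(v$exclusive_refseq_residues, t$exclusive_refseq_residues)
  expect_setequal(cur$library$record_id, t$record_id[t$retained])
  # partition: each record in exactly one outcome class
  expect_equal(sum(v$host_gene) + sum(v$removed_quality) +
                 nrow(cur$library), nrow(lib))
})

test_that("a library with no hits is retained as non-autonomous NE", {
  lib <- tibble::tibble(
    record_id = c("a", "b"), sequence = c(strrep("ACGT", 50), strrep("A", 119)),
    class_high = "Unknown", class_sub = NA_character_,
    genus = NA_character_, epithet = NA_character_,
    source_genome = NA_character_, evidence = NA_character_,
    lq_genome = FALSE)
  cur <- curate_library(lib)
  expect_equal(cur$verdicts$evidence, c("NE", "NE"))
  expect_true(all(cur$verdicts$non_autonomous))
  expect_equal(cur$library$record_id, "a")  # b fails quality
})

test_that("a record failing both host-gene and quality rules counts as host gene", {
  lib <- tibble::tibble(
    record_id = "hg", sequence = strrep("A", 100),  # < 120 nt
    class_high = "Unknown", class_sub = NA_character_,
    genus = NA_character_, epithet = NA_character_,
    source_genome = NA_character_, evidence = NA_character_,
    lq_genome = FALSE)
  hits <- make_hit("hg", frame = 1L, q_start = 0L, q_end = 30L,
                   category = "HOST_REFSEQ")
  cur <- curate_library(lib, hits)
  expect_true(cur$verdicts$host_gene)
  expect_false(cur$verdicts$removed_quality)
  expect_error(curate_library(lib, make_hit("ghost")), "absent")
})

test_that("per-subject exclusive mode requires one subject to carry the residues", {
  lib <- tibble::tibble(
    record_id = "c", sequence = strrep("A", 900),
    class_high = "Unknown", class_sub = NA_character_,
    genus = NA_character_, epithet = NA_character_,
    source_genome = NA_character_, evidence = NA_character_,
    lq_genome = FALSE)
  # two RefSeq subjects, each 60 exclusive residues; union = 120
  hits <- dplyr::bind_rows(
    make_hit("c", q_start = 0L, q_end = 60L, subject_id = "p1",
             category = "HOST_REFSEQ"),
    make_hit("c", q_start = 100L, q_end = 160L, subject_id = "p2",
             category = "HOST_REFSEQ"),
    make_hit("c", q_start = 200L, q_end = 260L, subject_id = "te1",
             category = "TE_PEP"))
  union_call <- curate_library(lib, hits, exclusive_mode = "union")
  per_subj <- curate_library(lib, hits, exclusive_mode = "per_subject")
  expect_true(union_call$verdicts$host_gene)
  expect_equal(union_call$verdicts$exclusive_refseq_residues, 120L)
  expect_false(per_subj$verdicts$host_gene)
  expect_equal(per_subj$verdicts$exclusive_refseq_residues, 60L)
})
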