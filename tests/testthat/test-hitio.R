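test_that("tabular BLAST hits parse with coordinate and frame conventions", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(c("cons7_5", "sp|P1", "98.0", "100", "2", "0", "1", "100",
                     "1", "100", "1e-50", "180"), collapse = "\t"), path)
  h <- read_blast_hits(path, "HOST_REFSEQ")
  expect_equal(h$consensus_id, "cons7")
  expect_equal(h$frame, 5L)
  expect_equal(h$q_start, 0L)
  expect_equal(h$q_end, 100L)
  expect_equal(h$category, "HOST_REFSEQ")

  # reversed query coordinates are normalized by swapping
  writeLines(paste(c("c1_2", "s", "90", "10", "1", "0", "20", "11",
                     "1", "10", "1e-5", "60"), collapse = "\t"), path)
  h2 <- read_blast_hits(path, "TE_PEP")
  expect_equal(c(h2$q_start, h2$q_end), c(10L, 20L))

  writeLines(character(0), path)
  expect_equal(nrow(read_blast_hits(path, "TE_PEP")), 0)

  writeLines("only\tthree\tcolumns", path)
  expect_error(read_blast_hits(path, "TE_PEP"), "line 1")
  writeLines(paste(c("noframe", "s", "90", "10", "1", "0", "1", "10",
                     "1", "10", "1e-5", "60"), collapse = "\t"), path)
  expect_error(read_blast_hits(path, "TE_PEP"), "frame suffix")
})

test_that("HMMER domain tables parse envelope coordinates and full-sequence stats", {
  path <- withr::local_tempfile(fileext = ".domtbl")
  writeLines(c("# comment", "#"), path)
  expect_equal(nrow(read_domtbl_hits(path)), 0)

  line <- paste("RT_dom - 120 cons3_2 - 400 5e-03 49.5 0.1 1 1 6e-03 6e-03",
                "48.0 0.1 1 51 8 58 10 60 0.95 some description here")
  writeLines(c("# target name ...", line), path)
  h <- read_domtbl_hits(path)
  expect_equal(h$consensus_id, "cons3")
  expect_equal(h$frame, 2L)
  expect_equal(c(h$q_start, h$q_end), c(9L, 60L))  # envelope 10..60
  expect_equal(h$evalue, 5e-3)    # full-sequence E-value, not domain
  expect_equal(h$bitscore, 49.5)  # parsing keeps sub-threshold hits
  expect_equal(h$category, "TE_HMM")

  writeLines("too few fields", path)
  expect_error(read_domtbl_hits(path), "line 1")
})

test_that("threshold filtering applies per-category inclusive rules", {
  hits <- dplyr::bind_rows(
    make_hit("a", category = "TE_HMM", evalue = 5e-4, bitscore = 49),   # out
    make_hit("a", category = "TE_HMM", evalue = 1e-3, bitscore = 50),   # in
    make_hit("a", category = "HOST_REFSEQ", evalue = 1e-3, bitscore = 10), # in
    make_hit("a", category = "HOST_REFSEQ", evalue = 2e-3, bitscore = 500), # out
    make_hit("a", category = "TE_PEP", evalue = 1e-4, bitscore = 20),   # in
    make_hit("a", category = "TE_PEP", evalue = 0.5, bitscore = 200)    # out
  )
  kept <- filter_hits(hits)
  expect_equal(nrow(kept), 3)
  expect_equal(kept$evalue, c(1e-3, 1e-3, 1e-4))
  # idempotent, output subset of input
  expect_identical(filter_hits(kept), kept)
})

test_that("nested-hit resolution keeps the highest-quality hit", {
  a <- make_hit("c", nt_start = 0L, nt_end = 300L, bitscore = 200,
                subject_id = "A")
  b <- make_hit("c", nt_start = 30L, nt_end = 150L, bitscore = 90,
                subject_id = "B")
  expect_equal(resolve_nested(dplyr::bind_rows(a, b))$subject_id, "A")
  # the container loses when it has lower quality
  a2 <- make_hit("c", nt_start = 0L, nt_end = 300L, bitscore = 90,
                 subject_id = "A")
  b2 <- make_hit("c", nt_start = 30L, nt_end = 150L, bitscore = 200,
                 subject_id = "B")
  expect_equal(resolve_nested(dplyr::bind_rows(a2, b2))$subject_id, "B")
  # disjoint hits survive
  c3 <- make_hit("c", nt_start = 400L, nt_end = 500L, bitscore = 10,
                 subject_id = "C")
  out <- resolve_nested(dplyr::bind_rows(a, b, c3))
  expect_setequal(out$subject_id, c("A", "C"))
  expect_error(resolve_nested(dplyr::bind_rows(a, make_hit("other",
    nt_start = 0L, nt_end = 9L))), "single consensus")
})

test_that("resolved hits contain no containment pair (property)", {
  withr::with_seed(21, {
    for (rep in 1:30) {
      n <- sample(3:12, 1)
      iv <- random_intervals(n, 600)
      hits <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
        make_hit("c", nt_start = iv$start[i], nt_end = iv$end[i],
                 bitscore = sample(40:300, 1), evalue = 10^-sample(3:30, 1),
                 subject_id = sprintf("s%d", i))
      }))
      out <- resolve_nested(hits)
      for (i in seq_len(nrow(out))) {
        for (j in seq_len(nrow(out))) {
          if (i != j) {
            expect_false(out$nt_start[i] >= out$nt_start[j] &&
                           out$nt_end[i] <= out$nt_end[j])
          }
        }
      }
    }
  })
})

test_that("adjacent and overlapping hits merge under the gap rule", {
  h <- function(s, e) make_hit("c", nt_start = s, nt_end = e)
  expect_equal(merge_hits(dplyr::bind_rows(h(10L, 50L), h(40L, 80L)),
                          gap_max_nt = 0),
               tibble::tibble(start = 10L, end = 80L))
  two <- dplyr::bind_rows(h(10L, 50L), h(55L, 80L))
  expect_equal(merge_hits(two, gap_max_nt = 30),
               tibble::tibble(start = 10L, end = 80L))
  expect_equal(merge_hits(two, gap_max_nt = 0),
               tibble::tibble(start = c(10L, 55L), end = c(50L, 80L)))
  expect_error(merge_hits(two, gap_max_nt = -1), "non-negative")
})

test_that("merged coverage equals the per-position oracle (property)", {
  withr::with_seed(33, {
    for (rep in 1:50) {
      L <- 500L
      iv <- random_intervals(sample(5:100, 1), L)
      hits <- dplyr::bind_rows(lapply(seq_len(nrow(iv)), function(i) {
        make_hit("c", nt_start = iv$start[i], nt_end = iv$end[i])
      }))
      merged <- merge_hits(hits, gap_max_nt = 0)
      expect_equal(sum(merged$end - merged$start),
                   sum(oracle_cover(iv$start, iv$end, L)))
      # and per position, not just total
      cov <- oracle_cover(merged$start, merged$end, L)
      expect_equal(cov, oracle_cover(iv$start, iv$end, L))
    }
  })
})

test_that("projection fills nt spans of 3x residue length", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(c("c1_4", "s", "90", "10", "1", "0", "1", "10",
                     "1", "10", "1e-5", "60"), collapse = "\t"), path)
  h <- read_blast_hits(path, "TE_PEP")
  lib <- tibble::tibble(record_id = "c1", sequence = strrep("A", 60))
  p <- project_hits(h, lib)
  expect_equal(p$nt_end - p$nt_start, 3L * (p$q_end - p$q_start))
  expect_equal(c(p$nt_start, p$nt_end), c(30L, 60L))
  expect_error(project_hits(h, tibble::tibble(record_id = "zz",
    sequence = "ACG")), "unknown consensus")
})
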