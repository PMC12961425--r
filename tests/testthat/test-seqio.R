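test_that("grammar headers parse into their fields", {
  f <- parse_te_header(
    "MycMob1.1_family-12-ZymTri_PE#LTR/Gypsy @Zymoseptoria tritici")
  expect_equal(f$class_high, "LTR")
  expect_equal(f$class_sub, "Gypsy")
  expect_equal(f$evidence, "PE")
  expect_equal(f$family_number, 12L)
  expect_equal(f$species_code, "ZymTri")
  expect_equal(f$genus, "Zymoseptoria")
  expect_equal(f$epithet, "tritici")
  expect_false(f$lq_genome)

  m <- parse_te_header(
    "MycMob2.0_family-7_member-3-MagOry_DA_LQGenome#DNA @Magnaporthe oryzae")
  expect_equal(m$member_number, 3L)
  expect_equal(m$family_number, 7L)
  expect_true(m$lq_genome)
  expect_true(is.na(m$class_sub))
})

test_that("plain headers yield unset metadata, with optional classification", {
  p <- parse_te_header(c("cons7", "rnd1_fam5#LTR/Gypsy", "x#DNA"))
  expect_equal(p$record_id, c("cons7", "rnd1_fam5", "x"))
  expect_equal(p$class_high, c("Unknown", "LTR", "DNA"))
  expect_equal(p$class_sub, c(NA, "Gypsy", NA))
  expect_true(all(is.na(p$evidence)))
})

test_that("header grammar round-trips losslessly (property)", {
  withr::with_seed(42, {
    fields <- random_header_fields(200)
    headers <- format_te_header(fields)
    back <- parse_te_header(headers)
    for (col in c("release", "family_number", "member_number",
                  "species_code", "evidence", "lq_genome", "class_high",
                  "class_sub", "genus", "epithet")) {
      expect_equal(back[[col]], fields[[col]], info = col)
    }
    expect_equal(format_te_header(back), headers)
  })
})

test_that("species codes are built from genus and epithet with x padding", {
  expect_equal(species_code("Zymoseptoria", "tritici"), "ZymTri")
  expect_equal(species_code("Fusarium", "oxysporum"), "FusOxy")
  expect_equal(species_code("Zy", "t-1"), "ZyxTxx")
})

test_that("FASTA round trip preserves records and rejects bad input", {
  path <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">cons1#LTR/Gypsy ZT001", "ACGTACGTacgt", ">cons2", "NNACGT"),
             path)
  lib <- read_te_library(path)
  expect_equal(lib$record_id, c("cons1", "cons2"))
  expect_equal(lib$sequence, c("ACGTACGTACGT", "NNACGT"))  # uppercased
  expect_equal(lib$source_genome, c("ZT001", NA))
  expect_equal(lib$class_high, c("LTR", "Unknown"))

  out <- withr::local_tempfile(fileext = ".fa")
  write_te_library(lib, out)
  expect_equal(read_te_library(out)$sequence, lib$sequence)

  writeLines(c(">a", "ACGT", ">a", "ACGT"), path)
  expect_error(read_te_library(path), "duplicate")
  writeLines(c(">a", "ACGRT"), path)
  expect_error(read_te_library(path), "position 4")
  writeLines(character(0), path)
  expect_error(read_te_library(path), "no FASTA")
})

test_that("n_fraction counts N case-insensitively", {
  expect_equal(n_fraction(paste0(strrep("A", 95), strrep("N", 5))), 0.05)
  expect_equal(n_fraction("ACGT"), 0)
  expect_equal(n_fraction(paste0(strrep("G", 37), "nnN")), 0.075)
})

test_that("six-frame translation follows the genetic code conventions", {
  tr <- translate_six_frames("ATGAAA")
  expect_equal(unname(tr["1"]), "MK")
  expect_equal(unname(tr["4"]), "FH")  # revcomp TTTCAT
  expect_equal(unname(translate_six_frames("ATGTAA")["1"]), "M*")
  expect_equal(unname(translate_six_frames("ATGNAAGGG")["1"]), "MXG")
  expect_error(translate_six_frames("AT"), "codon")
})

test_that("frame-1 translation of the reverse complement equals frame 4 (property)", {
  withr::with_seed(11, {
    for (i in 1:20) {
      s <- random_dna_str(sample(30:120, 1))
      rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
      expect_equal(translate_six_frames(rc)[["1"]],
                   translate_six_frames(s)[["4"]])
      expect_equal(translate_six_frames(rc)[["4"]],
                   translate_six_frames(s)[["1"]])
    }
  })
})

test_that("residue spans project to forward-strand nucleotide intervals", {
  expect_equal(residue_to_nt(1, 0, 1, 30), tibble::tibble(nt_start = 0L, nt_end = 3L))
  expect_equal(residue_to_nt(2, 9, 10, 31), tibble::tibble(nt_start = 28L, nt_end = 31L))
  expect_equal(residue_to_nt(4, 0, 1, 30), tibble::tibble(nt_start = 27L, nt_end = 30L))
  expect_error(residue_to_nt(1, 0, 11, 30), "outside frame")
})

test_that("projected intervals have length 3x span and stay inside [0, L) (property)", {
  withr::with_seed(5, {
    for (i in 1:200) {
      L <- sample(30:300, 1)
      frame <- sample(1:6, 1)
      flen <- (L - ifelse(frame <= 3, frame - 1, frame - 4)) %/% 3
      rs <- sample.int(flen, 1) - 1L
      re <- rs + sample.int(flen - rs, 1)
      nt <- residue_to_nt(frame, rs, re, L)
      expect_equal(nt$nt_end - nt$nt_start, 3L * (re - rs))
      expect_gte(nt$nt_start, 0L)
      expect_lte(nt$nt_end, L)
    }
  })
})
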