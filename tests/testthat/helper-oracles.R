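# Independent per-position brute-force oracles. These re-derive every
# quantity from boolean position arrays and never call the interval or
# comparison code they are used to check.

# boolean coverage array from raw [start, end) intervals
oracle_cover <- function(starts, ends, L) {
  covered <- logical(L)
  for (i in seq_along(starts)) {
    if (ends[i] > starts[i]) covered[(starts[i] + 1):ends[i]] <- TRUE
  }
  covered
}

# coverage with gaps of <= gap uncovered positions closed (interior only)
oracle_cover_gapped <- function(starts, ends, L, gap) {
  covered <- oracle_cover(starts, ends, L)
  if (!any(covered)) return(covered)
  runs <- rle(covered)
  stop_at <- cumsum(runs$lengths)
  start_at <- stop_at - runs$lengths + 1
  for (k in seq_along(runs$values)) {
    if (!runs$values[k] && k > 1 && k < length(runs$values) &&
        runs$lengths[k] <= gap) {
      covered[start_at[k]:stop_at[k]] <- TRUE
    }
  }
  covered
}

# RefSeq-exclusive positions given two raw interval lists
oracle_exclusive_nt <- function(ref_starts, ref_ends, te_starts, te_ends, L) {
  ref <- oracle_cover(ref_starts, ref_ends, L)
  te <- oracle_cover(te_starts, te_ends, L)
  sum(ref & !te)
}

# three-way position accounting for two feature sets on one seqid
oracle_three_way <- function(a_starts, a_ends, b_starts, b_ends, L) {
  a <- oracle_cover(a_starts, a_ends, L)
  b <- oracle_cover(b_starts, b_ends, L)
  c(shared = sum(a & b), unique_A = sum(a & !b), unique_B = sum(!a & b))
}

random_intervals <- function(n, L, max_len = NULL) {
  if (is.null(max_len)) max_len <- max(3L, L %/% 4L)
  s <- sample.int(L - 2L, n, replace = TRUE) - 1L
  len <- sample.int(max_len, n, replace = TRUE)
  tibble::tibble(start = s, end = pmin(s + len, L))
}

# grammar-valid random header fields for round-trip property tests
random_header_fields <- function(n) {
  rand_word <- function(k) {
    vapply(seq_len(k), function(i) {
      paste(sample(letters, sample(4:10, 1), replace = TRUE), collapse = "")
    }, character(1))
  }
  classes <- c("LTR", "DNA", "LINE", "SINE", "RC", "Unknown")
  subs <- c("Gypsy", "Copia", "hAT", "Tc1-Mariner", "L1", NA)
  member <- sample(c(TRUE, FALSE), n, replace = TRUE)
  genus <- paste0(toupper(substr(rand_word(n), 1, 1)), rand_word(n))
  epithet <- rand_word(n)
  tibble::tibble(
    record_id = NA_character_,
    release = sprintf("%d.%d", sample(1:3, n, TRUE), sample(0:9, n, TRUE)),
    family_number = sample(1:99999, n),
    member_number = ifelse(member, sample(1:999, n, TRUE), NA_integer_),
    species_code = species_code(genus, epithet),
    evidence = sample(c("PE", "DA", "NE"), n, TRUE),
    lq_genome = sample(c(TRUE, FALSE), n, TRUE),
    class_high = sample(classes, n, TRUE),
    class_sub = sample(subs, n, TRUE),
    genus = genus,
    epithet = epithet
  )
}

# minimal hit-tibble constructor for tests
make_hit <- function(consensus_id = "c1", frame = 1L, q_start = 0L,
                     q_end = 10L, subject_id = "s1",
                     category = "TE_PEP", evalue = 1e-10, bitscore = 100,
                     nt_start = NA_integer_, nt_end = NA_integer_,
                     subject_class_high = NA_character_,
                     subject_class_sub = NA_character_) {
  tibble::tibble(consensus_id = consensus_id, frame = frame,
                 q_start = q_start, q_end = q_end, subject_id = subject_id,
                 category = category,
                 subject_class_high = subject_class_high,
                 subject_class_sub = subject_class_sub,
                 evalue = evalue, bitscore = bitscore,
                 nt_start = nt_start, nt_end = nt_end)
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
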