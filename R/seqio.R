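#' Six-letter species code
#'
#' Builds the species code used inside family and member names: the first
#' three letters of the genus and the first three of the species epithet,
#' each with an initial capital ("Zymoseptoria tritici" -> "ZymTri").
#' Non-alphabetic characters are dropped first; a part shorter than three
#' letters is padded with "x". Collisions between species are tolerated
#' because the family/member number, not the code, is the unique key.
#'
#' @param genus,epithet Character vectors (recycled to a common length).
#' @return Character vector of six-letter codes.
#' @examples
#' species_code("Zymoseptoria", "tritici")
#' species_code("Zymoseptoria sp.", "x-1")
#' @export
species_code <- function(genus, epithet) {
  part <- function(x) {
    x <- gsub("[^A-Za-z]", "", as.character(x))
    x <- substr(x, 1, 3)
    x <- vapply(x, function(p) {
      if (nchar(p) < 3) p <- paste0(p, strrep("x", 3 - nchar(p)))
      paste0(toupper(substr(p, 1, 1)), tolower(substr(p, 2, 3)))
    }, character(1), USE.NAMES = FALSE)
    x
  }
  paste0(part(genus), part(epithet))
}

# Header grammar (internal regexes).
# Clustered:   MycMob<rel>_family-<n>-<CODE>_<EV>[_LQGenome]#<high>[/<sub>] @<Genus> <epithet>
# Unclustered: MycMob<rel>_family-<n>_member-<m>-<CODE>_<EV>[_LQGenome]#... @...
.re_tail <- " @([^ ]+) ([^ ]+)$"
.re_class <- "#([^/@ ]+)(?:/([^ ]+?))?"
.re_family <- paste0(
  "^MycMob([0-9]+(?:\\.[0-9]+)?)_family-([0-9]+)-([A-Za-z]{6})",
  "_(PE|DA|NE)(_LQGenome)?", .re_class, .re_tail
)
.re_member <- paste0(
  "^MycMob([0-9]+(?:\\.[0-9]+)?)_family-([0-9]+)_member-([0-9]+)-([A-Za-z]{6})",
  "_(PE|DA|NE)(_LQGenome)?", .re_class, .re_tail
)

empty_header_fields <- function(record_id = NA_character_) {
  tibble(
    record_id = record_id,
    release = NA_character_,
    family_number = NA_integer_,
    member_number = NA_integer_,
    species_code = NA_character_,
    evidence = NA_character_,
    lq_genome = FALSE,
    class_high = "Unknown",
    class_sub = NA_character_,
    genus = NA_character_,
    epithet = NA_character_
  )
}

#' Parse a TE library FASTA header
#'
#' Understands three header styles: the full clustered family grammar
#' (`MycMob1.1_family-12-ZymTri_PE#LTR/Gypsy @Zymoseptoria tritici`), the
#' unclustered member grammar (`..._family-12_member-3-ZymTri_...`), and the
#' plain RepeatMasker-style `id#class/subclass` or bare `id` headers emitted
#' by de novo curation tools. Plain headers yield unset metadata
#' (`evidence = NA`, `class_high = "Unknown"` unless a `#` classification is
#' present).
#'
#' @param header Character vector of header lines (without the leading `>`).
#' @return A tibble with one row per header and columns `record_id`,
#'   `release`, `family_number`, `member_number`, `species_code`, `evidence`,
#'   `lq_genome`, `class_high`, `class_sub`, `genus`, `epithet`.
#' @examples
#' parse_te_header("MycMob1.1_family-12-ZymTri_PE#LTR/Gypsy @Zymoseptoria tritici")
#' parse_te_header("rnd1_family5#DNA/hAT")
#' @export
parse_te_header <- function(header) {
  one <- function(h) {
    h <- trimws(h)
    m <- regmatches(h, regexec(.re_member, h))[[1]]
    if (length(m)) {
      out <- empty_header_fields()
      out$release <- m[2]
      out$family_number <- as.integer(m[3])
      out$member_number <- as.integer(m[4])
      out$species_code <- m[5]
      out$evidence <- m[6]
      out$lq_genome <- nzchar(m[7])
      out$class_high <- m[8]
      out$class_sub <- if (nzchar(m[9])) m[9] else NA_character_
      out$genus <- m[10]
      out$epithet <- m[11]
      out$record_id <- sub(" @.*$", "", h)
      return(out)
    }
    m <- regmatches(h, regexec(.re_family, h))[[1]]
    if (length(m)) {
      out <- empty_header_fields()
      out$release <- m[2]
      out$family_number <- as.integer(m[3])
      out$species_code <- m[4]
      out$evidence <- m[5]
      out$lq_genome <- nzchar(m[6])
      out$class_high <- m[7]
      out$class_sub <- if (nzchar(m[8])) m[8] else NA_character_
      out$genus <- m[9]
      out$epithet <- m[10]
      out$record_id <- sub(" @.*$", "", h)
      return(out)
    }
    # plain header: id token, optional '#high/sub' classification
    id <- strsplit(h, "[ \t]")[[1]][1]
    out <- empty_header_fields(record_id = id)
    cm <- regmatches(id, regexec("^(.*)#([^/#]+)(?:/(.+))?$", id))[[1]]
    if (length(cm)) {
      out$record_id <- cm[2]
      out$class_high <- cm[3]
      out$class_sub <- if (nzchar(cm[4])) cm[4] else NA_character_
    }
    out
  }
  bind_rows(lapply(header, one))
}

#' Format a TE library header from its fields
#'
#' The inverse of [parse_te_header()] for grammar-valid field sets:
#' `format_te_header(parse_te_header(h)) == h`. Rows lacking a
#' `family_number` are rendered in the plain style (`id#class/sub` when the
#' classification is informative, bare `id` otherwise).
#'
#' @param fields A tibble as returned by [parse_te_header()] (one or more
#'   rows).
#' @return Character vector of header strings.
#' @export
format_te_header <- function(fields) {
  vapply(seq_len(nrow(fields)), function(i) {
    f <- fields[i, ]
    if (is.na(f$family_number)) {
      cls <- if (!is.na(f$class_high) && (f$class_high != "Unknown" ||
                                          !is.na(f$class_sub))) {
        paste0("#", f$class_high,
               if (!is.na(f$class_sub)) paste0("/", f$class_sub) else "")
      } else ""
      return(paste0(f$record_id, cls))
    }
    block <- if (is.na(f$member_number)) {
      sprintf("family-%d-%s", f$family_number, f$species_code)
    } else {
      sprintf("family-%d_member-%d-%s", f$family_number, f$member_number,
              f$species_code)
    }
    paste0(
      "MycMob", f$release, "_", block,
      "_", f$evidence,
      if (isTRUE(f$lq_genome)) "_LQGenome" else "",
      "#", f$class_high,
      if (!is.na(f$class_sub)) paste0("/", f$class_sub) else "",
      " @", f$genus, " ", f$epithet
    )
  }, character(1))
}

#' Read a TE consensus library from FASTA
#'
#' Sequences are uppercased on read (soft-masking is discarded) and must use
#' the alphabet `A`, `C`, `G`, `T`, `N`. Headers are parsed with
#' [parse_te_header()]; duplicate record ids and illegal characters are
#' errors.
#'
#' For plain (non-grammar) headers, a second whitespace-separated token is
#' read as the record's source genome assembly id (the convention used when
#' representatives are labelled with the genome they came from), e.g.
#' `>cons1#LTR/Gypsy ZT001`.
#'
#' @param path Path to a FASTA file.
#' @return A *library tibble*: one row per record with `record_id`,
#'   `sequence`, the header fields of [parse_te_header()], and a
#'   `source_genome` column.
#' @export
read_te_library <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) {
    stop(sprintf("no FASTA records found in '%s'", path), call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  bad <- regexpr("[^ACGTN]", seqs)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop(sprintf(
      "illegal character '%s' at position %d of record '%s'",
      substr(seqs[i], bad[i], bad[i]), bad[i],
      strsplit(names(set)[i], "[ \t]")[[1]][1]
    ), call. = FALSE)
  }
  fields <- parse_te_header(names(set))
  dup <- fields$record_id[duplicated(fields$record_id)]
  if (length(dup)) {
    stop(sprintf("duplicate record id(s): %s",
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  }
  src <- vapply(strsplit(trimws(names(set)), "[ \t]+"), function(tok) {
    if (length(tok) >= 2) tok[2] else NA_character_
  }, character(1))
  src[!is.na(fields$release)] <- NA_character_  # grammar headers carry no assembly id
  mutate(fields, sequence = unname(seqs), source_genome = src,
         .after = record_id)
}

#' Write a TE consensus library to FASTA
#'
#' Headers are rendered with [format_te_header()]; sequences are wrapped at
#' 60 columns.
#'
#' @param library A library tibble (see [read_te_library()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_te_library <- function(library, path) {
  set <- Biostrings::BStringSet(setNames(library$sequence,
                                         format_te_header(library)))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Fraction of ambiguous (N) nucleotides
#'
#' @param sequence Character vector of nucleotide sequences (case
#'   insensitive).
#' @return Numeric vector in `[0, 1]`: count of `N` divided by length.
#' @examples
#' n_fraction("ACGTNNACGT")
#' @export
n_fraction <- function(sequence) {
  if (any(!nzchar(sequence))) stop("empty sequence", call. = FALSE)
  n <- nchar(gsub("[^Nn]", "", sequence))
  n / nchar(sequence)
}

#' Six-frame translation of a consensus sequence
#'
#' Frames 1-3 translate the forward strand starting at offsets 0-2; frames
#' 4-6 translate the reverse complement at offsets 0-2 (standard genetic
#' code). Trailing partial codons are dropped, stop codons are kept as `*`,
#' and any codon containing `N` is rendered as `X`.
#'
#' @param sequence A single nucleotide sequence (length >= 3).
#' @return Named character vector of six peptides (`"1"` to `"6"`).
#' @examples
#' translate_six_frames("ATGAAA")
#' @export
translate_six_frames <- function(sequence) {
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  if (L < 3) stop("sequence shorter than one codon", call. = FALSE)
  fwd <- Biostrings::DNAString(sequence)
  rev <- Biostrings::reverseComplement(fwd)
  tr <- function(s, off) {
    n <- 3L * ((length(s) - off) %/% 3L)
    if (n == 0L) return("")
    as.character(Biostrings::translate(
      Biostrings::subseq(s, start = off + 1L, width = n),
      if.fuzzy.codon = "X"
    ))
  }
  setNames(
    c(tr(fwd, 0L), tr(fwd, 1L), tr(fwd, 2L),
      tr(rev, 0L), tr(rev, 1L), tr(rev, 2L)),
    as.character(1:6)
  )
}

#' Project a residue span of a translated frame to consensus nucleotides
#'
#' Hits reported on translated frames are compared on one shared axis: the
#' forward strand of the consensus. For forward frame `f` in 1-3 a residue
#' span `[start, end)` maps to `[3*start + f - 1, 3*end + f - 1)`. For
#' reverse frames 4-6 the span is mapped on the reverse complement and then
#' mirrored: with `s' = 3*start + f - 4`, `e' = 3*end + f - 4`, the result is
#' `[L - e', L - s')` where `L` is the consensus length. The projected
#' interval always has length `3 * (end - start)`.
#'
#' @param frame Integer vector in 1..6.
#' @param res_start,res_end Residue span `[res_start, res_end)` (0-based
#'   half-open) on the translated frame.
#' @param consensus_length Length of the consensus in nucleotides.
#' @return A tibble with columns `nt_start`, `nt_end` (0-based half-open on
#'   the forward strand).
#' @examples
#' residue_to_nt(1, 0, 1, 30)   # first codon        -> [0, 3)
#' residue_to_nt(4, 0, 1, 30)   # first reverse codon -> [27, 30)
#' @export
residue_to_nt <- function(frame, res_start, res_end, consensus_length) {
  n <- max(length(frame), length(res_start), length(res_end),
           length(consensus_length))
  frame <- as.integer(rep_len(frame, n))
  res_start <- as.integer(rep_len(res_start, n))
  res_end <- as.integer(rep_len(res_end, n))
  L <- as.integer(rep_len(consensus_length, n))
  if (any(is.na(frame)) || any(frame < 1L | frame > 6L)) {
    stop("`frame` must be in 1..6", call. = FALSE)
  }
  if (any(res_end <= res_start) || any(res_start < 0L)) {
    stop("residue span must satisfy 0 <= start < end", call. = FALSE)
  }
  off <- ifelse(frame <= 3L, frame - 1L, frame - 4L)
  frame_len <- (L - off) %/% 3L
  if (any(res_end > frame_len)) {
    i <- which(res_end > frame_len)[1]
    stop(sprintf(
      "residue span [%d, %d) outside frame %d (frame length %d residues)",
      res_start[i], res_end[i], frame[i], frame_len[i]), call. = FALSE)
  }
  s_raw <- 3L * res_start + off
  e_raw <- 3L * res_end + off
  tibble(
    nt_start = ifelse(frame <= 3L, s_raw, L - e_raw),
    nt_end = ifelse(frame <= 3L, e_raw, L - s_raw)
  )
}
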