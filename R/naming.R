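#' Assign persistent family and member names
#'
#' Gives every clustered family and every unclustered member its library
#' name. Family numbers are assigned deterministically: clusters ordered by
#' descending size, ties broken by representative id. The representative
#' defines a family's species code, classification, and evidence code
#' (family evidence is propagated to members); members are numbered within
#' each family in lexicographic id order and carry their own species code
#' and `LQGenome` flag, following the member grammar.
#'
#' @param clusters A cluster tibble (`representative_id`, `member_id`).
#' @param library A library tibble covering every clustered id, with
#'   `genus`, `epithet`, `class_high`, `class_sub` filled.
#' @param verdicts Optional verdicts tibble from [curate_library()]
#'   supplying `evidence` and `lq_genome`; when absent, the library's own
#'   columns are used (missing evidence defaults to `NE`).
#' @param release Release string rendered into the names (e.g. `"1.1"`).
#' @return A list with `clustered` (one renamed record per family
#'   representative), `unclustered` (one renamed record per member), and
#'   `name_map` (`old_id`, `new_name`, `role`).
#' @export
assign_names <- function(clusters, library, verdicts = NULL,
                         release = "1.1") {
  if (any(duplicated(clusters$member_id))) {
    stop("a member id appears in more than one cluster", call. = FALSE)
  }
  missing <- setdiff(unique(c(clusters$representative_id,
                              clusters$member_id)), library$record_id)
  if (length(missing)) {
    stop(sprintf("cluster id(s) absent from the library: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (nrow(clusters) == 0) {
    empty <- library[0, , drop = FALSE]
    return(list(clustered = empty, unclustered = empty,
                name_map = tibble(old_id = character(),
                                  new_name = character(),
                                  role = character())))
  }

  lib <- library
  if (!is.null(verdicts)) {
    m <- match(lib$record_id, verdicts$consensus_id)
    lib$evidence <- ifelse(is.na(m), lib$evidence, verdicts$evidence[m])
    lib$lq_genome <- ifelse(is.na(m), lib$lq_genome, verdicts$lq_genome[m])
  }
  lib$evidence[is.na(lib$evidence)] <- "NE"
  lib$lq_genome[is.na(lib$lq_genome)] <- FALSE
  if (anyNA(lib$genus) || anyNA(lib$epithet)) {
    stop("every clustered record needs genus and epithet for its species code",
         call. = FALSE)
  }
  rownames_lib <- setNames(seq_len(nrow(lib)), lib$record_id)

  fam <- clusters |>
    group_by(representative_id) |>
    summarise(cluster_size = n(), .groups = "drop") |>
    arrange(desc(cluster_size), representative_id) |>
    mutate(family_number = row_number())

  render <- function(ids, family_number, member_number, evidence) {
    rows <- lib[rownames_lib[ids], , drop = FALSE]
    rows$release <- release
    rows$family_number <- family_number
    rows$member_number <- member_number
    rows$species_code <- species_code(rows$genus, rows$epithet)
    rows$evidence <- evidence
    rows$record_id <- format_te_header(rows)
    rows
  }

  clustered <- render(fam$representative_id, fam$family_number,
                      NA_integer_,
                      lib$evidence[rownames_lib[fam$representative_id]])

  members <- clusters |>
    left_join(fam, by = "representative_id") |>
    arrange(family_number, member_id) |>
    group_by(family_number) |>
    mutate(member_number = row_number()) |>
    dplyr::ungroup()
  fam_evidence <- lib$evidence[rownames_lib[members$representative_id]]
  unclustered <- render(members$member_id, members$family_number,
                        members$member_number, fam_evidence)

  name_map <- bind_rows(
    tibble(old_id = fam$representative_id,
           new_name = format_te_header(clustered), role = "representative"),
    tibble(old_id = members$member_id,
           new_name = format_te_header(unclustered), role = "member")
  )
  dup <- name_map$new_name[duplicated(name_map$new_name)]
  if (length(dup)) {
    stop(sprintf("name collision: %s", paste(unique(dup), collapse = ", ")),
         call. = FALSE)
  }
  list(clustered = clustered, unclustered = unclustered,
       name_map = name_map)
}

#' Write a name map as TSV
#'
#' @param name_map The `name_map` tibble of [assign_names()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_name_map_tsv <- function(name_map, path) {
  readr::write_tsv(name_map, path, progress = FALSE)
  invisible(path)
}
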