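#' Default run configuration
#'
#' Aggregates every tunable of the curation pipeline with its standard
#' default, as a plain list that round-trips through a YAML config file.
#'
#' @return A named list: hit thresholds, curation thresholds, clustering
#'   parameters, `merge_gap_nt`, `exclusive_mode`, `release`, and `seed`.
#' @export
default_config <- function() {
  list(
    release = "1.1",
    seed = 1L,
    merge_gap_nt = 30L,
    exclusive_mode = "union",
    hit_thresholds = unclass(hit_thresholds()),
    curation_thresholds = unclass(curation_thresholds()),
    cluster_params = unclass(cluster_params())
  )
}

#' Read / write a pipeline configuration
#'
#' @param path Path to a YAML file.
#' @return For `read_config()`, the configuration list (missing keys filled
#'   from [default_config()]).
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  utils::modifyList(default_config(), cfg)
}

#' @rdname read_config
#' @param config A configuration list.
#' @return For `write_config()`, `path` invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

config_thresholds <- function(config) {
  list(
    hit = do.call(hit_thresholds, config$hit_thresholds),
    curation = do.call(curation_thresholds, config$curation_thresholds),
    cluster = do.call(cluster_params, config$cluster_params)
  )
}

#' Run the end-to-end curation pipeline
#'
#' Ties the modules together in the library-construction order: family
#' clustering, host-gene removal, quality filtering, evidence labelling,
#' genome-quality flagging, and persistent naming. Records shorter than
#' the clustering minimum bypass clustering as singleton families (they
#' are then removed by the quality stage). After curation, clusters are
#' restricted to retained members; a cluster whose representative was
#' removed is re-represented by its longest remaining member. Species for
#' the naming stage come from the genome metadata of each record's source
#' assembly.
#'
#' @param library A library tibble (see [read_te_library()]).
#' @param hits A raw hit tibble (filtering is applied here).
#' @param genome_meta Genome metadata tibble (see
#'   [read_genome_metadata()]).
#' @param mapping Domain-classification mapping tibble.
#' @param config A configuration list (see [default_config()]).
#' @param out_dir Optional output directory; when given, the clustered and
#'   unclustered FASTA libraries, verdicts, name map, audit table, and the
#'   effective config are written there.
#' @return A list: `verdicts`, `clusters`, `named` (the [assign_names()]
#'   result), and `audit` (per-stage record counts).
#' @export
run_pipeline <- function(library, hits = NULL, genome_meta = NULL,
                         mapping = NULL, config = default_config(),
                         out_dir = NULL) {
  th <- config_thresholds(config)

  # species from genome metadata, for naming
  if (!is.null(genome_meta)) {
    sp <- strsplit(genome_meta$species, " ")
    m <- match(library$source_genome, genome_meta$assembly_id)
    fill <- !is.na(m) & is.na(library$genus)
    library$genus[fill] <- vapply(sp[m[fill]], `[`, character(1), 1)
    library$epithet[fill] <- vapply(sp[m[fill]], `[`, character(1), 2)
  }

  # clustering (records under the clustering minimum become singletons)
  clusterable <- nchar(library$sequence) >= th$cluster$min_length_nt
  clusters <- greedy_cluster(library[clusterable, , drop = FALSE],
                             th$cluster)
  if (any(!clusterable)) {
    clusters <- bind_rows(clusters, tibble(
      representative_id = library$record_id[!clusterable],
      member_id = library$record_id[!clusterable]))
  }

  # curation
  if (!is.null(hits)) hits <- filter_hits(hits, th$hit)
  cur <- curate_library(library, hits, genome_meta = genome_meta,
                        mapping = mapping, th = th$curation,
                        gap_max_nt = config$merge_gap_nt,
                        exclusive_mode = config$exclusive_mode)

  # restrict clusters to retained records; re-represent orphaned clusters
  retained_ids <- cur$library$record_id
  kept <- clusters[clusters$member_id %in% retained_ids, , drop = FALSE]
  lens <- setNames(nchar(library$sequence), library$record_id)
  fixed <- lapply(split(kept, kept$representative_id), function(cl) {
    if (cl$representative_id[1] %in% cl$member_id) return(cl)
    new_rep <- cl$member_id[order(-lens[cl$member_id], cl$member_id)][1]
    cl$representative_id <- new_rep
    cl
  })
  clusters_retained <- arrange(bind_rows(fixed), representative_id,
                               member_id)

  named <- assign_names(clusters_retained, cur$library,
                        verdicts = cur$verdicts, release = config$release)

  audit <- tibble(
    stage = c("input", "host_gene_removed", "quality_removed", "retained",
              "families"),
    n = c(nrow(library), sum(cur$verdicts$host_gene),
          sum(cur$verdicts$removed_quality), length(retained_ids),
          length(unique(clusters_retained$representative_id)))
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_te_library(named$clustered, file.path(out_dir, "clustered.fa"))
    write_te_library(named$unclustered, file.path(out_dir, "unclustered.fa"))
    write_verdicts_tsv(cur$verdicts, file.path(out_dir, "verdicts.tsv"))
    write_name_map_tsv(named$name_map, file.path(out_dir, "name_map.tsv"))
    write_cluster_table(clusters_retained,
                        file.path(out_dir, "clusters.tsv"))
    readr::write_tsv(audit, file.path(out_dir, "audit.tsv"),
                     progress = FALSE)
    write_config(config, file.path(out_dir, "config.yml"))
  }

  list(verdicts = cur$verdicts, clusters = clusters_retained,
       named = named, audit = audit)
}
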