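# End-to-end pipeline: curated class -> fragments -> MMPs -> cliffs ->
# MMS/MMSP -> networks -> exports, with a run manifest of stage counts.

#' Run the full AC network pipeline
#'
#' Executes fragmentation, MMP enumeration, cliff detection, series
#' extraction, series-pair detection, and builds both the compound-level
#' AC network and the reduced MMS network. When `output_dir` is given,
#' all stage tables, both networks (GraphML and SIF + attribute CSVs)
#' and the JSON manifest are written there.
#'
#' @param compounds Curated class tibble: `compound_id`, `smiles`, `pki`.
#' @param rules A [size_rules()] object.
#' @param output_dir Optional output directory.
#' @param mode Fragmentation mode, see [fragment_compounds()].
#' @return An `ac_pipeline` object: list with `compounds`, `fragments`,
#'   `mmps`, `cliffs`, `mms`, `mmsps`, `network` (`ac_network` or
#'   `NULL`), `reduced` (`reduced_network` or `NULL`), `coverage`, and
#'   `manifest` (named list of stage counts).
#' @export
run_ac_pipeline <- function(compounds, rules = size_rules(), output_dir = NULL,
                            mode = c("acyclic", "exocyclic")) {
  rules <- as_size_rules(rules)
  mode <- match.arg(mode)
  if (is.null(compounds) || !nrow(compounds)) {
    cli::cli_inform("Empty curated class: nothing to do.")
    res <- structure(
      list(
        compounds = tibble::tibble(
          compound_id = character(0), smiles = character(0), pki = numeric(0)
        ),
        fragments = NULL, mmps = NULL, cliffs = NULL, mms = NULL, mmsps = NULL,
        network = NULL, reduced = NULL, coverage = NULL,
        manifest = empty_manifest()
      ),
      class = "ac_pipeline"
    )
    if (!is.null(output_dir)) write_pipeline(res, output_dir)
    return(res)
  }
  stopifnot(all(c("compound_id", "smiles", "pki") %in% names(compounds)))
  compounds <- dplyr::arrange(
    tibble::as_tibble(compounds), .data$compound_id
  )
  if (anyDuplicated(compounds$compound_id)) {
    cli::cli_abort("Compound ids must be unique within an activity class.")
  }

  fragments <- fragment_compounds(compounds, rules = rules, mode = mode)
  mmps <- enumerate_mmps(fragments, rules = rules)
  cliffs <- detect_cliffs(mmps, compounds, rules = rules)

  if (!nrow(cliffs)) {
    cli::cli_warn("No MMP-cliffs found; networks are empty.")
    mms <- extract_mms(fragments, character(0), compounds)
    mms <- dplyr::mutate(mms, n_intra_cliffs = integer(0), ac_propensity = numeric(0))
    network <- NULL
    reduced <- NULL
    mmsps <- find_mmsps(mms, rules = rules)
    coverage <- NULL
  } else {
    ac_ids <- ac_compounds(cliffs)
    mms <- extract_mms(fragments, ac_ids, compounds)
    mms <- intra_mms_cliffs(mms, cliffs)
    mmsps <- find_mmsps(mms, rules = rules)
    network <- build_ac_network(cliffs, compounds)
    reduced <- build_reduced_network(mms, mmsps)
    coverage <- cluster_coverage(network, reduced)
  }

  manifest <- build_manifest(compounds, fragments, mmps, cliffs, mms, mmsps,
    network, reduced
  )
  res <- structure(
    list(
      compounds = compounds, fragments = fragments, mmps = mmps,
      cliffs = cliffs, mms = mms, mmsps = mmsps,
      network = network, reduced = reduced, coverage = coverage,
      manifest = manifest
    ),
    class = "ac_pipeline"
  )
  if (!is.null(output_dir)) write_pipeline(res, output_dir)
  res
}

empty_manifest <- function() {
  list(
    n_compounds = 0L, n_fragments = 0L, n_mmps = 0L, n_cliffs = 0L,
    n_ac_compounds = 0L, n_coordinated = 0L, n_isolated = 0L,
    n_components = 0L, n_clusters = 0L, largest_cluster_cliffs = 0L,
    n_mms = 0L, n_mmsps = 0L, n_singleton_mms = 0L
  )
}

build_manifest <- function(compounds, fragments, mmps, cliffs, mms, mmsps,
                           network, reduced) {
  m <- empty_manifest()
  m$n_compounds <- nrow(compounds)
  m$n_fragments <- nrow(fragments)
  m$n_mmps <- nrow(mmps)
  m$n_cliffs <- nrow(cliffs)
  if (!is.null(network)) {
    g <- glance.ac_network(network)
    m$n_ac_compounds <- g$n_compounds
    m$n_coordinated <- g$n_coordinated
    m$n_isolated <- g$n_isolated
    m$n_components <- g$n_components
    m$n_clusters <- g$n_clusters
    m$largest_cluster_cliffs <- g$largest_cluster_cliffs
  }
  m$n_mms <- nrow(mms)
  m$n_mmsps <- nrow(mmsps)
  if (!is.null(reduced)) m$n_singleton_mms <- reduced$n_singletons
  m
}

#' @export
print.ac_pipeline <- function(x, ...) {
  m <- x$manifest
  cat("AC network pipeline run\n")
  for (k in names(m)) cat(sprintf("  %-24s %s\n", k, m[[k]]))
  invisible(x)
}

write_pipeline <- function(p, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  jsonlite::write_json(
    p$manifest, file.path(dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  if (!is.null(p$compounds) && nrow(p$compounds)) {
    write_curated_class(p$compounds, file.path(dir, "compounds.tsv"))
  }
  if (!is.null(p$fragments)) {
    write_fragment_index(p$fragments, file.path(dir, "fragments.tsv"))
  }
  if (!is.null(p$mmps)) readr::write_tsv(p$mmps, file.path(dir, "mmps.tsv"), progress = FALSE)
  if (!is.null(p$cliffs)) write_cliffs(p$cliffs, file.path(dir, "cliffs.tsv"))
  if (!is.null(p$mms)) {
    write_mms_tables(
      p$mms, p$mmsps,
      file.path(dir, "mms.tsv"), file.path(dir, "mmsps.tsv")
    )
  }
  if (!is.null(p$network)) {
    write_network_graphml(p$network, file.path(dir, "ac_network.graphml"))
    write_network_sif(p$network, file.path(dir, "ac_network"))
  }
  if (!is.null(p$reduced)) {
    write_network_graphml(p$reduced, file.path(dir, "reduced_network.graphml"))
    write_network_sif(p$reduced, file.path(dir, "reduced_network"))
  }
  if (!is.null(p$coverage)) {
    readr::write_tsv(p$coverage, file.path(dir, "cluster_coverage.tsv"), progress = FALSE)
  }
  invisible(dir)
}

# ---- configuration -----------------------------------------------------

#' Default pipeline configuration
#'
#' Thresholds default to the standard analog-series values: core at
#' least twice the substituent, substituent at most 13 heavy atoms,
#' exchange difference at most 8, cliff threshold dpKi >= 2.0,
#' consolidation window 1.0 pKi units.
#'
#' @return Named list, serializable to YAML with [write_pipeline_config()].
#' @export
default_pipeline_config <- function() {
  list(
    rules = unclass(size_rules()),
    consistency_window = 1.0,
    fragmentation_mode = "acyclic",
    organism = "Homo sapiens",
    col_map = as.list(chembl_col_map()),
    output_dir = "acnet_output",
    seed = 1L
  )
}

#' Read / write a pipeline configuration (YAML)
#'
#' @param path YAML file path.
#' @return For `read_pipeline_config()`, the configuration list with
#'   defaults filled in; for `write_pipeline_config()`, `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_pipeline_config()
  for (k in names(base)) {
    if (is.null(cfg[[k]])) {
      cfg[[k]] <- base[[k]]
    } else if (is.list(base[[k]])) {
      for (kk in names(base[[k]])) {
        if (is.null(cfg[[k]][[kk]])) cfg[[k]][[kk]] <- base[[k]][[kk]]
      }
    }
  }
  cfg
}

#' @rdname read_pipeline_config
#' @param config Configuration list.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
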