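# Compound-level AC networks and their MMS-level reduction.

#' Build the compound-level activity cliff network
#'
#' Nodes are AC compounds, edges are MMP-cliffs. Each node is assigned a
#' role: `"high"` if the compound is the more potent partner in all of
#' its cliffs, `"low"` if the less potent partner in all, `"mixed"`
#' otherwise. Clusters are connected components.
#'
#' @param cliffs Tibble from [detect_cliffs()] (non-empty).
#' @param compounds Curated class tibble with `compound_id` and `pki`.
#' @return An `ac_network` object: list with `nodes` (tibble:
#'   `compound_id`, `pki`, `role`, `degree`, `component`), `edges` (the
#'   cliffs plus `component` and `isolated`), and `graph` (igraph).
#' @export
build_ac_network <- function(cliffs, compounds) {
  if (!nrow(cliffs)) {
    cli::cli_abort("Cannot build an AC network from an empty cliff set.")
  }
  ids <- ac_compounds(cliffs)
  g <- igraph::graph_from_data_frame(
    cliffs[, c("high_id", "low_id")],
    directed = FALSE,
    vertices = ids
  )
  comp <- igraph::components(g)
  membership <- comp$membership[ids]
  n_high <- stats::setNames(integer(length(ids)), ids)
  n_low <- n_high
  th <- table(cliffs$high_id)
  tl <- table(cliffs$low_id)
  n_high[names(th)] <- as.integer(th)
  n_low[names(tl)] <- as.integer(tl)
  role <- dplyr::case_when(
    n_high > 0L & n_low == 0L ~ "high",
    n_low > 0L & n_high == 0L ~ "low",
    .default = "mixed"
  )
  pki <- stats::setNames(compounds$pki, compounds$compound_id)
  nodes <- tibble::tibble(
    compound_id = ids,
    pki = unname(pki[ids]),
    role = role,
    degree = unname(igraph::degree(g)[ids]),
    component = unname(membership)
  )
  comp_sizes <- comp$csize
  edges <- cliffs
  edges$component <- unname(membership[match(edges$high_id, ids)])
  edges$isolated <- comp_sizes[edges$component] == 2L
  structure(
    list(nodes = nodes, edges = edges, graph = g),
    class = "ac_network"
  )
}

#' Classify cliffs as coordinated or isolated
#'
#' An isolated cliff is an edge forming its own two-node connected
#' component; all other cliffs are coordinated (they share compounds with
#' other cliffs).
#'
#' @param network An `ac_network` from [build_ac_network()].
#' @return Named list: `n_coordinated`, `n_isolated`.
#' @export
classify_cliffs <- function(network) {
  stopifnot(inherits(network, "ac_network"))
  n_iso <- sum(network$edges$isolated)
  list(n_coordinated = nrow(network$edges) - n_iso, n_isolated = n_iso)
}

#' Summarise AC network clusters
#'
#' One row per connected component with node and edge counts. Following
#' the counting convention in which isolated cliffs (two-node components)
#' are reported separately from clusters, the `is_cluster` flag marks
#' components with more than two nodes.
#'
#' @param network An `ac_network`.
#' @return Tibble: `component`, `n_compounds`, `n_cliffs`, `is_cluster`.
#' @export
ac_clusters <- function(network) {
  stopifnot(inherits(network, "ac_network"))
  nodes <- dplyr::count(network$nodes, .data$component, name = "n_compounds")
  edges <- dplyr::count(network$edges, .data$component, name = "n_cliffs")
  dplyr::left_join(nodes, edges, by = "component") |>
    dplyr::mutate(
      n_cliffs = dplyr::coalesce(.data$n_cliffs, 0L),
      is_cluster = .data$n_compounds > 2L
    ) |>
    dplyr::arrange(dplyr::desc(.data$n_cliffs))
}

#' Build the reduced MMS-level network
#'
#' Nodes are matching molecular series, edges are MMSP relationships.
#' Each node carries the three numeric display attributes of the reduced
#' representation: `n_members` (node size), `max_pki` (color value) and
#' `ac_propensity` (border thickness). Mapping these numbers to pixels
#' and colors is left to the renderer.
#'
#' @param mms Tibble from [extract_mms()] after [intra_mms_cliffs()].
#' @param mmsps Tibble from [find_mmsps()].
#' @return A `reduced_network` object: list with `nodes`, `edges`,
#'   `graph` (igraph) and `n_singletons` (series without any MMSP).
#' @export
build_reduced_network <- function(mms, mmsps) {
  if (!all(c("n_intra_cliffs", "ac_propensity") %in% names(mms))) {
    cli::cli_abort("Run {.fn intra_mms_cliffs} on the MMS table first.")
  }
  g <- igraph::graph_from_data_frame(
    mmsps[, c("mms_a", "mms_b")],
    directed = FALSE,
    vertices = mms$mms_id
  )
  comp <- igraph::components(g)
  nodes <- mms
  nodes$degree <- unname(igraph::degree(g)[mms$mms_id])
  nodes$component <- unname(comp$membership[mms$mms_id])
  edges <- mmsps
  if (nrow(edges)) {
    edges$component <- nodes$component[match(edges$mms_a, nodes$mms_id)]
  } else {
    edges$component <- integer(0)
  }
  structure(
    list(
      nodes = nodes, edges = edges, graph = g,
      n_singletons = sum(nodes$degree == 0L)
    ),
    class = "reduced_network"
  )
}

#' Map AC clusters onto reduced-network clusters
#'
#' For every pair of (AC network component, reduced network component),
#' reports the fraction of the AC component's cliff edges whose compound
#' pair lies inside at least one MMS of the reduced component. Because a
#' compound pair can occur in series of different components, fractions
#' for one AC cluster may overlap across reduced clusters; their union
#' always covers every cliff (cliff-coverage invariant).
#'
#' @param network An `ac_network`.
#' @param reduced A `reduced_network`.
#' @return Tibble: `ac_component`, `red_component`, `n_cliffs`,
#'   `n_covered`, `coverage` (fraction in `[0, 1]`).
#' @export
cluster_coverage <- function(network, reduced) {
  stopifnot(inherits(network, "ac_network"), inherits(reduced, "reduced_network"))
  # member pair -> reduced component lookup
  pair_comp <- purrr::map2(
    reduced$nodes$members, reduced$nodes$component,
    function(m, comp) {
      ids <- sort(unique(m$compound_id), method = "radix")
      if (length(ids) < 2L) return(NULL)
      pr <- utils::combn(ids, 2L)
      tibble::tibble(key = pair_key(pr[1L, ], pr[2L, ]), red_component = comp)
    }
  ) |>
    dplyr::bind_rows() |>
    dplyr::distinct()
  edges <- tibble::tibble(
    key = pair_key(network$edges$high_id, network$edges$low_id),
    ac_component = network$edges$component
  )
  totals <- dplyr::count(edges, .data$ac_component, name = "n_cliffs")
  covered <- dplyr::inner_join(edges, pair_comp, by = "key",
    relationship = "many-to-many"
  ) |>
    dplyr::distinct(.data$key, .data$ac_component, .data$red_component) |>
    dplyr::count(.data$ac_component, .data$red_component, name = "n_covered")
  tidyr::crossing(
    ac_component = sort(unique(edges$ac_component)),
    red_component = sort(unique(reduced$nodes$component))
  ) |>
    dplyr::left_join(totals, by = "ac_component") |>
    dplyr::left_join(covered, by = c("ac_component", "red_component")) |>
    dplyr::mutate(
      n_covered = dplyr::coalesce(.data$n_covered, 0L),
      coverage = .data$n_covered / .data$n_cliffs
    )
}

#' @export
print.ac_network <- function(x, ...) {
  cls <- ac_clusters(x)
  cc <- classify_cliffs(x)
  cat(sprintf(
    "AC network: %d compounds, %d cliffs (%d coordinated, %d isolated), %d clusters (>2 nodes)\n",
    nrow(x$nodes), nrow(x$edges), cc$n_coordinated, cc$n_isolated, sum(cls$is_cluster)
  ))
  invisible(x)
}

#' @export
print.reduced_network <- function(x, ...) {
  cat(sprintf(
    "Reduced AC network: %d MMS nodes (%d singletons), %d MMSP edges\n",
    nrow(x$nodes), x$n_singletons, nrow(x$edges)
  ))
  invisible(x)
}

# ---- broom-style accessors --------------------------------------------

#' Tidy network objects
#'
#' Returns the edge table (default) or node table of a network as a
#' tibble.
#'
#' @param x An `ac_network` or `reduced_network`.
#' @param what `"edges"` or `"nodes"`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.ac_network <- function(x, what = c("edges", "nodes"), ...) {
  what <- match.arg(what)
  tibble::as_tibble(x[[what]])
}

#' @rdname tidy.ac_network
#' @export
tidy.reduced_network <- function(x, what = c("edges", "nodes"), ...) {
  what <- match.arg(what)
  out <- x[[what]]
  if (what == "nodes" && "members" %in% names(out)) {
    out$member_ids <- vapply(
      out$members,
      function(m) paste(sort(unique(m$compound_id), method = "radix"), collapse = ";"),
      character(1)
    )
    out$members <- NULL
  }
  tibble::as_tibble(out)
}

#' One-row network summaries
#'
#' @param x An `ac_network` or `reduced_network`.
#' @param ... Unused.
#' @return A one-row tibble of summary counts.
#' @export
glance.ac_network <- function(x, ...) {
  cls <- ac_clusters(x)
  cc <- classify_cliffs(x)
  tibble::tibble(
    n_compounds = nrow(x$nodes),
    n_cliffs = nrow(x$edges),
    n_coordinated = cc$n_coordinated,
    n_isolated = cc$n_isolated,
    n_components = nrow(cls),
    n_clusters = sum(cls$is_cluster),
    largest_cluster_cliffs = max(cls$n_cliffs)
  )
}

#' @rdname glance.ac_network
#' @export
glance.reduced_network <- function(x, ...) {
  tibble::tibble(
    n_mms = nrow(x$nodes),
    n_mmsps = nrow(x$edges),
    n_connected_mms = sum(x$nodes$degree > 0L),
    n_singleton_mms = x$n_singletons,
    n_components = length(unique(x$nodes$component)),
    mean_propensity = mean(x$nodes$ac_propensity)
  )
}

# ---- export ------------------------------------------------------------

igraph_with_attrs <- function(net) {
  if (inherits(net, "ac_network")) {
    nodes <- net$nodes
    edges <- net$edges |>
      dplyr::transmute(
        from = .data$high_id, to = .data$low_id,
        delta_pki = .data$delta_pki, core = .data$core_smiles,
        isolated = .data$isolated
      )
  } else {
    nodes <- tidy.reduced_network(net, "nodes")
    edges <- net$edges
    if (nrow(edges)) {
      edges <- dplyr::transmute(edges,
        from = .data$mms_a, to = .data$mms_b,
        meta_core = .data$meta_core_key
      )
    } else {
      edges <- tibble::tibble(from = character(0), to = character(0), meta_core = character(0))
    }
  }
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
}

#' Export a network as GraphML
#'
#' Writes the network with all node and edge attributes as GraphML,
#' loadable by Cytoscape and other viewers.
#'
#' @param net An `ac_network` or `reduced_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(net, path) {
  igraph::write_graph(igraph_with_attrs(net), path, format = "graphml")
  invisible(path)
}

#' Export a network as SIF plus attribute tables
#'
#' Writes `<prefix>.sif` (one interaction line per edge plus orphan node
#' lines), `<prefix>_nodes.csv` and `<prefix>_edges.csv`, the simple
#' text format combination used with Cytoscape.
#'
#' @param net An `ac_network` or `reduced_network`.
#' @param prefix Output path prefix.
#' @return Character vector of the three paths, invisibly.
#' @export
write_network_sif <- function(net, prefix) {
  if (inherits(net, "ac_network")) {
    rel <- "cliff"
    from <- net$edges$high_id
    to <- net$edges$low_id
    nodes <- net$nodes
    node_ids <- nodes$compound_id
  } else {
    rel <- "mmsp"
    from <- net$edges$mms_a
    to <- net$edges$mms_b
    nodes <- tidy.reduced_network(net, "nodes")
    node_ids <- nodes$mms_id
  }
  sif_path <- paste0(prefix, ".sif")
  lines <- sprintf("%s\t%s\t%s", from, rel, to)
  orphans <- setdiff(node_ids, c(from, to))
  writeLines(c(lines, orphans), sif_path)
  node_path <- paste0(prefix, "_nodes.csv")
  edge_path <- paste0(prefix, "_edges.csv")
  readr::write_csv(nodes, node_path, progress = FALSE)
  readr::write_csv(tibble::as_tibble(net$edges), edge_path, progress = FALSE)
  invisible(c(sif_path, node_path, edge_path))
}
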