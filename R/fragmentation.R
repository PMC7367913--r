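# Systematic single-cut fragmentation under analog-series size rules.

#' Fragment compounds by single-cut decomposition
#'
#' Cuts every acyclic single bond between two heavy atoms of each
#' compound, yielding a core and a substituent per cut, and keeps the
#' decompositions that satisfy the size rules: the core must have at
#' least `core_to_sub_ratio` times as many heavy atoms as the
#' substituent, and the substituent at most `max_sub_heavy` heavy atoms.
#' Ring bonds and bonds to hydrogen are never cut. The core is completed
#' with a hydrogen at the cut position; its identity (`core_key`) is the
#' canonical SMILES of the core with a dummy-atom marker `*` at the
#' substitution site, so symmetry-equivalent sites collapse to a single
#' key and two fragments share a `core_key` exactly when their cores are
#' the same molecule substituted at the same position.
#'
#' @param compounds Data frame with columns `compound_id` and `smiles`
#'   (additional columns are ignored). Structures must parse to single
#'   connected molecules.
#' @param rules A [size_rules()] object.
#' @param mode `"acyclic"` (default) cuts every acyclic single bond
#'   between heavy atoms; `"exocyclic"` restricts cuts to bonds with at
#'   least one ring-atom terminus.
#' @return Tibble of fragmentation records: `compound_id`, `core_key`
#'   (marked canonical SMILES, the core-plus-site identity), `core_smiles`
#'   (hydrogen-completed canonical SMILES of the core), `substituent_key`
#'   (marked canonical SMILES of the substituent), `core_heavy`,
#'   `sub_heavy`. Deduplicated per compound on
#'   (`core_key`, `substituent_key`).
#' @examples
#' \dontrun{
#' fragment_compounds(data.frame(compound_id = "tol", smiles = "Cc1ccccc1"))
#' }
#' @export
fragment_compounds <- function(compounds, rules = size_rules(),
                               mode = c("acyclic", "exocyclic")) {
  rules <- as_size_rules(rules)
  mode <- match.arg(mode)
  stopifnot(all(c("compound_id", "smiles") %in% names(compounds)))
  empty <- tibble::tibble(
    compound_id = character(0), core_key = character(0),
    core_smiles = character(0), substituent_key = character(0),
    core_heavy = integer(0), sub_heavy = integer(0)
  )
  if (!nrow(compounds)) return(empty)
  ids <- as.character(compounds$compound_id)
  can <- canonical_smiles(compounds$smiles)
  if (any(is.na(can))) {
    cli::cli_abort(
      "Structure{?s} failed to parse for compound{?s} {.val {ids[is.na(can)]}}."
    )
  }
  graphs <- mol_graphs(stats::setNames(can, paste0("i", seq_along(can))))

  frag_graphs <- list()
  meta <- list()
  for (ci in seq_along(ids)) {
    g <- graphs[[paste0("i", ci)]]
    if (is.null(g)) {
      cli::cli_abort("Structure failed to parse for compound {.val {ids[ci]}}.")
    }
    cuts <- enumerate_cut_sides(g, rules, mode)
    for (cut in cuts) {
      key <- length(frag_graphs)
      frag_graphs[[key + 1L]] <- subgraph_with_mark(g, cut$core, cut$core_attach)
      frag_graphs[[key + 2L]] <- subgraph_with_mark(g, cut$core)
      frag_graphs[[key + 3L]] <- subgraph_with_mark(g, cut$sub, cut$sub_attach)
      meta[[length(meta) + 1L]] <- tibble::tibble(
        compound_id = ids[ci],
        core_heavy = cut$core_heavy,
        sub_heavy = cut$sub_heavy
      )
    }
  }
  if (!length(meta)) return(empty)
  names(frag_graphs) <- paste0("f", seq_along(frag_graphs))
  smis <- graphs_to_smiles(frag_graphs)
  rec <- dplyr::bind_rows(meta)
  rec$core_key <- unname(smis[seq(1L, length(smis), by = 3L)])
  rec$core_smiles <- unname(smis[seq(2L, length(smis), by = 3L)])
  rec$substituent_key <- unname(smis[seq(3L, length(smis), by = 3L)])
  if (any(is.na(rec$core_key) | is.na(rec$substituent_key))) {
    cli::cli_abort("Internal error: a fragment failed to canonicalize.")
  }
  rec |>
    dplyr::distinct(.data$compound_id, .data$core_key, .data$substituent_key,
      .keep_all = TRUE
    ) |>
    dplyr::select(
      "compound_id", "core_key", "core_smiles", "substituent_key",
      "core_heavy", "sub_heavy"
    ) |>
    dplyr::arrange(.data$compound_id, .data$core_key, .data$substituent_key)
}

#' Enumerate single-cut decompositions of one molecule
#'
#' Convenience wrapper around [fragment_compounds()] for a single SMILES.
#'
#' @param smiles One SMILES string.
#' @inheritParams fragment_compounds
#' @return Tibble of fragmentation records (see [fragment_compounds()]).
#' @examples
#' \dontrun{
#' enumerate_cuts("Cc1ccccc1")  # toluene: one cut (benzene core, methyl)
#' }
#' @export
enumerate_cuts <- function(smiles, rules = size_rules(),
                           mode = c("acyclic", "exocyclic")) {
  stopifnot(length(smiles) == 1L)
  fragment_compounds(
    tibble::tibble(compound_id = smiles, smiles = smiles),
    rules = rules, mode = mode
  )
}

# Enumerate cut candidates of one molecular graph and apply the size
# rules. Returns a list of lists: core (atom indices), sub, core_attach,
# sub_attach, core_heavy, sub_heavy. Dummy atoms are never counted as
# heavy and bonds to them are never cut; a cut orientation qualifies when
# core_heavy >= ratio * sub_heavy and 1 <= sub_heavy <= max_sub_heavy.
enumerate_cut_sides <- function(g, rules, mode = "acyclic") {
  nb <- nrow(g$bonds)
  if (!nb) return(list())
  n_atoms <- nrow(g$atoms)
  ig <- igraph::graph_from_edgelist(cbind(g$bonds$a, g$bonds$b), directed = FALSE)
  if (igraph::vcount(ig) < n_atoms) {
    ig <- igraph::add_vertices(ig, n_atoms - igraph::vcount(ig))
  }
  bridge_ids <- igraph::bridges(ig)
  is_heavy <- !(g$atoms$elem %in% c("H", "*"))
  ring_atom <- rep(FALSE, n_atoms)
  nonbridge <- setdiff(seq_len(nb), as.integer(bridge_ids))
  ring_atom[c(g$bonds$a[nonbridge], g$bonds$b[nonbridge])] <- TRUE
  out <- list()
  for (e in as.integer(bridge_ids)) {
    a <- g$bonds$a[e]
    b <- g$bonds$b[e]
    if (g$bonds$order[e] != 1L) next
    if (!is_heavy[a] || !is_heavy[b]) next
    if (mode == "exocyclic" && !ring_atom[a] && !ring_atom[b]) next
    ig2 <- igraph::delete_edges(ig, e)
    comp <- igraph::components(ig2)$membership
    side_a <- which(comp == comp[a])
    side_b <- which(comp == comp[b])
    h_a <- sum(is_heavy[side_a])
    h_b <- sum(is_heavy[side_b])
    orientations <- list(
      list(core = side_a, sub = side_b, core_attach = a, sub_attach = b,
           core_heavy = h_a, sub_heavy = h_b),
      list(core = side_b, sub = side_a, core_attach = b, sub_attach = a,
           core_heavy = h_b, sub_heavy = h_a)
    )
    for (o in orientations) {
      if (o$sub_heavy >= 1L && o$sub_heavy <= rules$max_sub_heavy &&
          o$core_heavy >= rules$core_to_sub_ratio * o$sub_heavy) {
        out[[length(out) + 1L]] <- o
      }
    }
  }
  out
}

#' Write a fragment index to TSV
#'
#' @param fragments Tibble from [fragment_compounds()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fragment_index <- function(fragments, path) {
  readr::write_tsv(fragments, path, progress = FALSE)
  invisible(path)
}
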