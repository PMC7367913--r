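# Matched molecular pair enumeration by shared-core indexing, and
# MMP-cliff detection.

#' Enumerate matched molecular pairs from fragmentation records
#'
#' Groups fragmentation records by core identity; within each core group,
#' every pair of distinct compounds with distinct substituents whose
#' substituent size difference is at most `max_exchange_diff` heavy atoms
#' forms an MMP. Each unordered compound pair is reported once: when
#' several cores relate the same pair, the representative with the
#' largest core (i.e. the smallest transformation) is retained.
#'
#' @param fragments Tibble from [fragment_compounds()] for one activity
#'   class.
#' @param rules A [size_rules()] object.
#' @return Tibble of MMPs: `compound_a`, `compound_b` (sorted so
#'   `compound_a < compound_b`), `core_key`, `core_smiles`,
#'   `substituent_a`, `substituent_b`, `core_heavy`, `exchange_diff`.
#' @export
enumerate_mmps <- function(fragments, rules = size_rules()) {
  rules <- as_size_rules(rules)
  empty <- tibble::tibble(
    compound_a = character(0), compound_b = character(0),
    core_key = character(0), core_smiles = character(0),
    substituent_a = character(0), substituent_b = character(0),
    core_heavy = integer(0), exchange_diff = integer(0)
  )
  if (!nrow(fragments)) return(empty)
  f <- dplyr::select(
    fragments, "compound_id", "core_key", "core_smiles",
    "substituent_key", "core_heavy", "sub_heavy"
  )
  pairs <- dplyr::inner_join(
    f, f,
    by = c("core_key", "core_smiles", "core_heavy"),
    suffix = c("_a", "_b"),
    relationship = "many-to-many"
  ) |>
    dplyr::filter(
      .data$compound_id_a < .data$compound_id_b,
      .data$substituent_key_a != .data$substituent_key_b,
      abs(.data$sub_heavy_a - .data$sub_heavy_b) <= rules$max_exchange_diff
    )
  if (!nrow(pairs)) return(empty)
  pairs |>
    dplyr::mutate(exchange_diff = abs(.data$sub_heavy_a - .data$sub_heavy_b)) |>
    # one MMP per unordered compound pair: keep the largest core
    dplyr::arrange(
      .data$compound_id_a, .data$compound_id_b,
      dplyr::desc(.data$core_heavy), .data$core_key, .data$substituent_key_a
    ) |>
    dplyr::distinct(.data$compound_id_a, .data$compound_id_b, .keep_all = TRUE) |>
    dplyr::transmute(
      compound_a = .data$compound_id_a,
      compound_b = .data$compound_id_b,
      core_key = .data$core_key,
      core_smiles = .data$core_smiles,
      substituent_a = .data$substituent_key_a,
      substituent_b = .data$substituent_key_b,
      core_heavy = .data$core_heavy,
      exchange_diff = .data$exchange_diff
    )
}

#' Detect MMP-cliffs
#'
#' An MMP-cliff is an MMP whose two compounds differ in potency by at
#' least `min_delta_pki` (default 2.0, a 100-fold difference in Ki). The
#' pair is oriented so that `high_id` is the more potent compound.
#'
#' @param mmps Tibble from [enumerate_mmps()].
#' @param compounds Curated class tibble with `compound_id` and `pki`.
#' @param rules A [size_rules()] object.
#' @return Tibble of cliffs: `high_id`, `low_id`, `pki_high`, `pki_low`,
#'   `delta_pki`, `core_key`, `core_smiles`, `substituent_high`,
#'   `substituent_low`, `exchange_diff`.
#' @export
detect_cliffs <- function(mmps, compounds, rules = size_rules()) {
  rules <- as_size_rules(rules)
  empty <- tibble::tibble(
    high_id = character(0), low_id = character(0),
    pki_high = numeric(0), pki_low = numeric(0), delta_pki = numeric(0),
    core_key = character(0), core_smiles = character(0),
    substituent_high = character(0), substituent_low = character(0),
    exchange_diff = integer(0)
  )
  if (!nrow(mmps)) return(empty)
  pki <- stats::setNames(compounds$pki, compounds$compound_id)
  need <- unique(c(mmps$compound_a, mmps$compound_b))
  missing_ids <- need[!(need %in% names(pki)) | is.na(pki[need])]
  if (length(missing_ids)) {
    cli::cli_abort("No pKi value for compound{?s} {.val {missing_ids}}.")
  }
  hits <- mmps |>
    dplyr::mutate(
      pki_a = unname(pki[.data$compound_a]),
      pki_b = unname(pki[.data$compound_b]),
      delta_pki = abs(.data$pki_a - .data$pki_b)
    ) |>
    dplyr::filter(.data$delta_pki >= rules$min_delta_pki)
  if (!nrow(hits)) return(empty)
  hits |>
    dplyr::transmute(
      high_id = ifelse(.data$pki_a >= .data$pki_b, .data$compound_a, .data$compound_b),
      low_id = ifelse(.data$pki_a >= .data$pki_b, .data$compound_b, .data$compound_a),
      pki_high = pmax(.data$pki_a, .data$pki_b),
      pki_low = pmin(.data$pki_a, .data$pki_b),
      delta_pki = .data$delta_pki,
      core_key = .data$core_key,
      core_smiles = .data$core_smiles,
      substituent_high = ifelse(.data$pki_a >= .data$pki_b, .data$substituent_a, .data$substituent_b),
      substituent_low = ifelse(.data$pki_a >= .data$pki_b, .data$substituent_b, .data$substituent_a),
      exchange_diff = .data$exchange_diff
    )
}

#' Compounds participating in at least one cliff
#'
#' @param cliffs Tibble from [detect_cliffs()].
#' @return Character vector of AC compound ids, sorted.
#' @export
ac_compounds <- function(cliffs) {
  sort(unique(c(cliffs$high_id, cliffs$low_id)), method = "radix")
}

#' Write MMP-cliffs to TSV
#'
#' @param cliffs Tibble from [detect_cliffs()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cliffs <- function(cliffs, path) {
  readr::write_tsv(cliffs, path, progress = FALSE)
  invisible(path)
}
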