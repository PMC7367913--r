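# Matching molecular series (MMS) extraction and series-pair (MMSP)
# detection via second-round core fragmentation.

mms_id_for <- function(core_key) {
  paste0("MMS_", substr(vapply(core_key, cli::hash_md5, character(1)), 1L, 10L))
}

#' Extract matching molecular series from AC compounds
#'
#' Restricts fragmentation records to compounds that participate in at
#' least one MMP-cliff and groups them by core identity. Every core
#' carried by two or more distinct AC compounds becomes a matching
#' molecular series (MMS): analogs distinguished only by the substituent
#' at a single site. Series of exactly two members account for isolated
#' cliffs. A compound may belong to several MMSs (one per qualifying
#' core).
#'
#' @param fragments Tibble from [fragment_compounds()].
#' @param ac_ids Character vector of AC compound ids (see
#'   [ac_compounds()]).
#' @param compounds Optional curated class tibble with `compound_id` and
#'   `pki`; when given, member pKi values and the series maximum
#'   (`max_pki`) are attached.
#' @return Tibble with one row per MMS: `mms_id` (deterministic hash of
#'   the core identity), `core_key`, `core_smiles`, `n_members`,
#'   `max_pki`, and a `members` list-column of tibbles
#'   (`compound_id`, `substituent_key`, `sub_heavy`, `pki`).
#' @export
extract_mms <- function(fragments, ac_ids, compounds = NULL) {
  empty <- tibble::tibble(
    mms_id = character(0), core_key = character(0), core_smiles = character(0),
    n_members = integer(0), max_pki = numeric(0), members = list()
  )
  f <- fragments[fragments$compound_id %in% ac_ids, , drop = FALSE]
  if (!nrow(f)) return(empty)
  pki <- if (!is.null(compounds)) {
    stats::setNames(compounds$pki, compounds$compound_id)
  } else {
    stats::setNames(numeric(0), character(0))
  }
  f |>
    dplyr::mutate(pki = unname(pki[.data$compound_id])) |>
    dplyr::group_by(.data$core_key, .data$core_smiles) |>
    dplyr::filter(dplyr::n_distinct(.data$compound_id) >= 2L) |>
    dplyr::arrange(.data$compound_id, .by_group = TRUE) |>
    dplyr::summarise(
      n_members = dplyr::n_distinct(.data$compound_id),
      max_pki = if (all(is.na(.data$pki))) NA_real_ else max(.data$pki, na.rm = TRUE),
      members = list(dplyr::pick(
        "compound_id", "substituent_key", "sub_heavy", "pki"
      )),
      .groups = "drop"
    ) |>
    dplyr::mutate(mms_id = mms_id_for(.data$core_key)) |>
    dplyr::select(
      "mms_id", "core_key", "core_smiles", "n_members", "max_pki", "members"
    ) |>
    dplyr::arrange(.data$core_key)
}

#' Count intra-series cliffs and compute AC propensity
#'
#' For each MMS, counts the member pairs that appear in the class-level
#' cliff set and derives the AC propensity: the percentage of all
#' possible member pairs that form an AC,
#' `100 * n_intra_cliffs / choose(n_members, 2)`.
#'
#' @param mms Tibble from [extract_mms()].
#' @param cliffs Tibble from [detect_cliffs()].
#' @return `mms` with columns `n_intra_cliffs` and `ac_propensity` added.
#' @examples
#' \dontrun{
#' # members with pKi 5.0 / 5.1 / 7.5: two of the three pairs are cliffs,
#' # propensity 100 * 2/3 = 66.67
#' }
#' @export
intra_mms_cliffs <- function(mms, cliffs) {
  if (any(mms$n_members < 2L)) {
    cli::cli_abort("Every MMS must have at least two members.")
  }
  cliff_keys <- pair_key(cliffs$high_id, cliffs$low_id)
  counts <- vapply(mms$members, function(m) {
    ids <- sort(unique(m$compound_id), method = "radix")
    if (length(ids) < 2L) return(0L)
    pr <- utils::combn(ids, 2L)
    sum(pair_key(pr[1L, ], pr[2L, ]) %in% cliff_keys)
  }, integer(1))
  mms$n_intra_cliffs <- counts
  mms$ac_propensity <- 100 * counts / choose(mms$n_members, 2L)
  mms
}

pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Relate series through core-MMPs (MMS pairs)
#'
#' Subjects every distinct MMS-core to a second round of single-cut
#' fragmentation under the same size rules. Two distinct MMS-cores are
#' structurally analogous when they share a second-round core (meta-core)
#' carrying both the original substitution site and the new cut site at
#' matching positions, with distinct exchanged core substituents whose
#' size difference is at most `max_exchange_diff`. Each qualifying pair
#' of series is an MMS pair (MMSP); one MMSP is reported per unordered
#' pair of series, retaining the largest shared meta-core.
#'
#' @param mms Tibble from [extract_mms()].
#' @param rules A [size_rules()] object.
#' @return Tibble of MMSPs: `mms_a`, `mms_b`, `meta_core_key` (canonical
#'   SMILES with `[1*]` marking the original substitution site and `[2*]`
#'   the core-transformation site), `core_substituent_a`,
#'   `core_substituent_b`, `exchange_diff`.
#' @export
find_mmsps <- function(mms, rules = size_rules()) {
  rules <- as_size_rules(rules)
  empty <- tibble::tibble(
    mms_a = character(0), mms_b = character(0), meta_core_key = character(0),
    core_substituent_a = character(0), core_substituent_b = character(0),
    exchange_diff = integer(0)
  )
  if (nrow(mms) < 2L) return(empty)
  cores <- unique(mms$core_key)
  graphs <- mol_graphs(stats::setNames(cores, paste0("c", seq_along(cores))))

  frag_graphs <- list()
  meta <- list()
  for (ci in seq_along(cores)) {
    g <- graphs[[paste0("c", ci)]]
    if (is.null(g)) next
    star <- which(g$atoms$elem == "*")
    if (length(star) != 1L) next
    for (cut in enumerate_cut_sides(g, rules)) {
      # the meta-core must retain the original substitution site
      if (!(star %in% cut$core)) next
      core_g <- subgraph_with_mark(g, cut$core, cut$core_attach, mark_iso = 2L)
      core_g$atoms$iso[core_g$atoms$elem == "*" & core_g$atoms$iso == 0L] <- 1L
      sub_g <- subgraph_with_mark(g, cut$sub, cut$sub_attach)
      frag_graphs[[length(frag_graphs) + 1L]] <- core_g
      frag_graphs[[length(frag_graphs) + 1L]] <- sub_g
      meta[[length(meta) + 1L]] <- tibble::tibble(
        core_key = cores[ci],
        meta_core_heavy = cut$core_heavy,
        core_sub_heavy = cut$sub_heavy
      )
    }
  }
  if (!length(meta)) return(empty)
  names(frag_graphs) <- paste0("f", seq_along(frag_graphs))
  smis <- graphs_to_smiles(frag_graphs)
  rec <- dplyr::bind_rows(meta)
  rec$meta_core_key <- unname(smis[seq(1L, length(smis), by = 2L)])
  rec$core_substituent <- unname(smis[seq(2L, length(smis), by = 2L)])
  rec <- rec[!is.na(rec$meta_core_key) & !is.na(rec$core_substituent), , drop = FALSE]
  rec <- dplyr::distinct(rec)

  id_of <- stats::setNames(mms_id_for(cores), cores)
  pairs <- dplyr::inner_join(
    rec, rec,
    by = c("meta_core_key", "meta_core_heavy"),
    suffix = c("_a", "_b"),
    relationship = "many-to-many"
  ) |>
    dplyr::filter(
      .data$core_key_a != .data$core_key_b,
      .data$core_substituent_a != .data$core_substituent_b,
      abs(.data$core_sub_heavy_a - .data$core_sub_heavy_b) <= rules$max_exchange_diff
    )
  if (!nrow(pairs)) return(empty)
  pairs |>
    dplyr::mutate(
      mms_a = pmin(unname(id_of[.data$core_key_a]), unname(id_of[.data$core_key_b])),
      mms_b = pmax(unname(id_of[.data$core_key_a]), unname(id_of[.data$core_key_b])),
      sub_a = ifelse(id_of[.data$core_key_a] <= id_of[.data$core_key_b],
        .data$core_substituent_a, .data$core_substituent_b
      ),
      sub_b = ifelse(id_of[.data$core_key_a] <= id_of[.data$core_key_b],
        .data$core_substituent_b, .data$core_substituent_a
      ),
      exchange_diff = abs(.data$core_sub_heavy_a - .data$core_sub_heavy_b)
    ) |>
    dplyr::arrange(
      .data$mms_a, .data$mms_b, dplyr::desc(.data$meta_core_heavy),
      .data$meta_core_key, .data$sub_a
    ) |>
    dplyr::distinct(.data$mms_a, .data$mms_b, .keep_all = TRUE) |>
    dplyr::transmute(
      mms_a = .data$mms_a,
      mms_b = .data$mms_b,
      meta_core_key = .data$meta_core_key,
      core_substituent_a = .data$sub_a,
      core_substituent_b = .data$sub_b,
      exchange_diff = .data$exchange_diff
    )
}

#' Write MMS and MMSP tables to TSV
#'
#' The MMS table is written flat (one row per series, member compound ids
#' joined with `;`).
#'
#' @param mms Tibble from [extract_mms()] (after [intra_mms_cliffs()]).
#' @param mmsps Tibble from [find_mmsps()].
#' @param mms_path,mmsp_path Output file paths.
#' @return Invisibly, a list of the two paths.
#' @export
write_mms_tables <- function(mms, mmsps, mms_path, mmsp_path) {
  flat <- mms |>
    dplyr::mutate(
      member_ids = vapply(
        .data$members,
        function(m) paste(sort(unique(m$compound_id), method = "radix"), collapse = ";"),
        character(1)
      )
    ) |>
    dplyr::select(-"members")
  readr::write_tsv(flat, mms_path, progress = FALSE)
  readr::write_tsv(mmsps, mmsp_path, progress = FALSE)
  invisible(list(mms = mms_path, mmsp = mmsp_path))
}
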