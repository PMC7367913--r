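# R-group tables: the SAR deliverable for selected series and series
# pairs.

#' Build the R-group table of a series
#'
#' One row per MMS member with its substituent (R group, attachment
#' marked by `*`) and pKi, sorted by descending potency. Intra-series
#' cliffs are annotated per row (`cliff_partners`) and as a row-index
#' pair table attached as the `cliff_pairs` attribute.
#'
#' @param mms Tibble from [extract_mms()].
#' @param mms_id Identifier of the series to tabulate.
#' @param cliffs Tibble from [detect_cliffs()].
#' @return An `rgroup_table`: tibble with columns `compound_id`,
#'   `r_group`, `pki`, `cliff_partners`, with attributes `core_key`,
#'   `core_smiles` and `cliff_pairs` (tibble of `row_high`, `row_low`).
#' @export
mms_to_table <- function(mms, mms_id, cliffs) {
  row <- mms[mms$mms_id == mms_id, , drop = FALSE]
  if (nrow(row) != 1L) {
    cli::cli_abort("MMS {.val {mms_id}} not found.")
  }
  m <- row$members[[1L]] |>
    dplyr::distinct(.data$compound_id, .keep_all = TRUE) |>
    dplyr::arrange(dplyr::desc(.data$pki), .data$compound_id)
  keys <- pair_key(cliffs$high_id, cliffs$low_id)
  partners <- vapply(m$compound_id, function(id) {
    others <- setdiff(m$compound_id, id)
    hit <- others[pair_key(id, others) %in% keys]
    paste(hit, collapse = ";")
  }, character(1))
  tab <- tibble::tibble(
    compound_id = m$compound_id,
    r_group = m$substituent_key,
    pki = m$pki,
    cliff_partners = unname(partners)
  )
  pairs <- utils::combn(seq_len(nrow(tab)), 2L)
  in_cliff <- pair_key(tab$compound_id[pairs[1L, ]], tab$compound_id[pairs[2L, ]]) %in% keys
  cliff_pairs <- tibble::tibble(
    row_high = pairs[1L, in_cliff],
    row_low = pairs[2L, in_cliff]
  )
  structure(
    tab,
    core_key = row$core_key,
    core_smiles = row$core_smiles,
    mms_id = mms_id,
    cliff_pairs = cliff_pairs,
    class = c("rgroup_table", class(tab))
  )
}

#' Build the paired R-group tables of an MMS pair
#'
#' Returns the two series tables side by side with the core
#' transformation that relates them: the shared meta-core and the two
#' exchanged core substituents. With `flag_shared = TRUE`, R groups
#' occurring in both series are flagged in each table (`shared` column),
#' supporting joint analysis of chemically similar cores.
#'
#' @param mmsps Tibble from [find_mmsps()].
#' @param mms_a,mms_b The two series identifiers (order as in `mmsps` or
#'   swapped).
#' @param mms Tibble from [extract_mms()].
#' @param cliffs Tibble from [detect_cliffs()].
#' @param flag_shared Flag R groups common to both series (default
#'   `FALSE`).
#' @return List with `table_a`, `table_b` (each an `rgroup_table`) and
#'   `core_transformation` (one-row tibble: `meta_core_key`,
#'   `core_substituent_a`, `core_substituent_b`).
#' @export
mmsp_to_tables <- function(mmsps, mms_a, mms_b, mms, cliffs, flag_shared = FALSE) {
  hit <- mmsps[
    (mmsps$mms_a == mms_a & mmsps$mms_b == mms_b) |
      (mmsps$mms_a == mms_b & mmsps$mms_b == mms_a), ,
    drop = FALSE
  ]
  if (nrow(hit) != 1L) {
    cli::cli_abort("No MMSP between {.val {mms_a}} and {.val {mms_b}}.")
  }
  swapped <- hit$mms_a != mms_a
  ta <- mms_to_table(mms, mms_a, cliffs)
  tb <- mms_to_table(mms, mms_b, cliffs)
  if (flag_shared) {
    shared <- intersect(ta$r_group, tb$r_group)
    ta$shared <- ta$r_group %in% shared
    tb$shared <- tb$r_group %in% shared
  }
  list(
    table_a = ta,
    table_b = tb,
    core_transformation = tibble::tibble(
      meta_core_key = hit$meta_core_key,
      core_substituent_a = if (swapped) hit$core_substituent_b else hit$core_substituent_a,
      core_substituent_b = if (swapped) hit$core_substituent_a else hit$core_substituent_b
    )
  )
}

#' @export
print.rgroup_table <- function(x, ...) {
  cat(sprintf(
    "R-group table for %s (core %s), %d members, %d intra-series cliffs\n",
    attr(x, "mms_id"), attr(x, "core_smiles"), nrow(x), nrow(attr(x, "cliff_pairs"))
  ))
  NextMethod()
}

#' Write an R-group table to CSV
#'
#' The core identity is written as comment-style header columns
#' (`core_key`, `core_smiles`) repeated on every row so the file stands
#' alone.
#'
#' @param table An `rgroup_table` from [mms_to_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_rgroup_table <- function(table, path) {
  out <- tibble::as_tibble(table)
  out$core_key <- attr(table, "core_key")
  out$core_smiles <- attr(table, "core_smiles")
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Export fragments (cores or substituents) as SDF
#'
#' Writes marked SMILES fragments as an SDF file with the attachment
#' point encoded as a dummy atom, for use in structure-aware tools.
#'
#' @param keys Character vector of marked canonical SMILES.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fragments_sdf <- function(keys, path) {
  nm <- names(keys)
  if (is.null(nm)) nm <- keys
  sdf <- suppressWarnings(
    ChemmineOB::convertFormat("SMI", "SDF", paste0(keys, " ", nm, collapse = "\n"))
  )
  writeLines(sdf, path)
  invisible(path)
}
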