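# Curation of raw ChEMBL-style activity records into one consolidated
# pKi value per compound.

#' Convert Ki in nanomolar to pKi
#'
#' pKi is the negative decadic logarithm of Ki expressed in molar units,
#' so for Ki in nM: pKi = 9 - log10(Ki).
#'
#' @param ki_nM Positive numeric vector of Ki values in nanomolar.
#' @return Numeric vector of pKi values.
#' @examples
#' to_pki(1)    # 9
#' to_pki(100)  # 7
#' @export
to_pki <- function(ki_nM) {
  if (!is.numeric(ki_nM) || any(is.na(ki_nM)) || any(ki_nM <= 0)) {
    cli::cli_abort("Ki values must be positive numbers (got a non-positive or missing value).")
  }
  9 - log10(ki_nM)
}

#' Filter raw activity records to qualifying Ki measurements
#'
#' Applies the selection rules used to assemble high-confidence activity
#' classes from a ChEMBL-style extract: direct single-protein target
#' relationship ("D"), assay confidence score 9, human target, equilibrium
#' constants (Ki) with exact "=" relation, nanomolar units, and a positive
#' numeric value. Records with an unparseable value or a missing required
#' field are skipped with a warning, never dropped silently.
#'
#' @param records Data frame of activity measurements with columns
#'   `compound_id`, `smiles`, `target_id`, `standard_type`,
#'   `standard_relation`, `standard_value`, `standard_units`,
#'   `assay_confidence`, `target_relationship`, `organism`.
#' @param target_id Target identifier to select (e.g. a ChEMBL target ID).
#' @param organism Organism string for "human targets" (default
#'   `"Homo sapiens"`).
#' @return Tibble of qualifying records, input order preserved.
#' @export
filter_activity_records <- function(records, target_id, organism = "Homo sapiens") {
  stopifnot(is.character(target_id) || is.numeric(target_id), length(target_id) == 1L)
  required <- c(
    "compound_id", "smiles", "target_id", "standard_type", "standard_relation",
    "standard_value", "standard_units", "assay_confidence", "target_relationship",
    "organism"
  )
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols)) {
    cli::cli_abort("Activity records lack required column{?s} {.field {missing_cols}}.")
  }
  records <- tibble::as_tibble(records)
  val <- suppressWarnings(as.numeric(records$standard_value))
  broken <- which(is.na(val) & !is.na(records$standard_value)) # unparseable
  incomplete <- which(
    is.na(records$compound_id) | is.na(records$smiles) | is.na(records$standard_value)
  )
  skip <- union(broken, incomplete)
  if (length(skip)) {
    cli::cli_warn(
      "Skipped {length(skip)} record{?s} with missing or unparseable fields (row{?s} {.val {head(skip, 5)}}{if (length(skip) > 5) ' ...' else ''})."
    )
  }
  keep <- !(seq_len(nrow(records)) %in% skip) &
    records$target_id == as.character(target_id) &
    records$organism == organism &
    records$target_relationship == "D" &
    records$assay_confidence == 9L &
    records$standard_type == "Ki" &
    records$standard_relation == "=" &
    records$standard_units == "nM" &
    !is.na(val) & val > 0
  keep[is.na(keep)] <- FALSE
  out <- records[keep, , drop = FALSE]
  out$standard_value <- val[keep]
  out
}

#' Consolidate per-compound pKi measurements
#'
#' Multiple qualifying measurements for the same compound are averaged on
#' the pKi scale, provided they all fall within the same order of
#' magnitude (pKi range at most `window`); otherwise the compound is
#' disregarded.
#'
#' @param measurements Data frame with columns `compound_id` and `pki`
#'   (one row per measurement); an optional `smiles` column is carried
#'   through (first value per compound).
#' @param window Maximum allowed pKi spread among a compound's
#'   measurements (default 1.0, i.e. a 10-fold Ki range).
#' @return Tibble with columns `compound_id`, (`smiles`,) `pki`,
#'   `n_measurements`; one row per retained compound.
#' @examples
#' consolidate_compounds(
#'   data.frame(compound_id = c("a", "a", "b"), pki = c(6.0, 6.9, 7.2))
#' )
#' @export
consolidate_compounds <- function(measurements, window = 1.0) {
  stopifnot(is.numeric(window), window > 0)
  if (!nrow(measurements)) {
    cli::cli_abort("No measurements to consolidate.")
  }
  if (any(!is.finite(measurements$pki))) {
    cli::cli_abort("All pKi values must be finite.")
  }
  has_smiles <- "smiles" %in% names(measurements)
  out <- measurements |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$compound_id) |>
    dplyr::summarise(
      smiles = if (has_smiles) dplyr::first(.data$smiles) else NA_character_,
      spread = max(.data$pki) - min(.data$pki),
      pki = mean(.data$pki),
      n_measurements = dplyr::n(),
      .groups = "drop"
    )
  rejected <- out$spread > window
  if (any(rejected)) {
    cli::cli_inform(
      "Disregarded {sum(rejected)} compound{?s} with inconsistent measurements (pKi spread > {window})."
    )
  }
  out <- out[!rejected, c("compound_id", if (has_smiles) "smiles", "pki", "n_measurements")]
  dplyr::arrange(out, .data$compound_id)
}

#' Curate an activity class from raw records
#'
#' Full curation: record-level filtering ([filter_activity_records()]),
#' structure standardization (desalting to the largest covalent component,
#' canonicalization; unparseable structures are dropped with a warning),
#' Ki-to-pKi conversion and per-compound consolidation
#' ([consolidate_compounds()]). Stereochemistry is preserved as given:
#' records differing only in stereo annotation remain distinct compounds.
#'
#' @inheritParams filter_activity_records
#' @param window Consolidation window in pKi units (default 1.0).
#' @return Curated class tibble: `compound_id`, `smiles` (canonical),
#'   `pki`, `n_measurements`.
#' @export
curate_activity_class <- function(records, target_id, organism = "Homo sapiens",
                                  window = 1.0) {
  recs <- filter_activity_records(records, target_id, organism = organism)
  if (!nrow(recs)) {
    return(tibble::tibble(
      compound_id = character(0), smiles = character(0),
      pki = numeric(0), n_measurements = integer(0)
    ))
  }
  std <- desalt_smiles(recs$smiles)
  bad <- is.na(std)
  if (any(bad)) {
    cli::cli_warn("Dropped {sum(bad)} record{?s} whose structure failed to parse.")
    recs <- recs[!bad, , drop = FALSE]
    std <- std[!bad]
  }
  # one structure per compound_id; conflicting structures use the first one
  recs$smiles <- std
  conflicts <- recs |>
    dplyr::distinct(.data$compound_id, .data$smiles) |>
    dplyr::count(.data$compound_id) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(conflicts)) {
    cli::cli_warn(
      "{nrow(conflicts)} compound{?s} carried more than one distinct structure; keeping the first occurrence."
    )
  }
  recs$pki <- to_pki(recs$standard_value)
  consolidate_compounds(
    recs[, c("compound_id", "smiles", "pki")],
    window = window
  )
}

#' Read activity records from a delimited file
#'
#' Reads a TSV/CSV activity extract and renames columns to the standard
#' names expected by [filter_activity_records()] via `col_map`.
#'
#' @param path File path (delimiter inferred from extension: `.csv` comma,
#'   otherwise tab).
#' @param col_map Named character vector mapping standard names to the
#'   file's column names. Defaults to ChEMBL export conventions.
#' @return Tibble of activity records.
#' @export
read_activity_records <- function(path, col_map = chembl_col_map()) {
  reader <- if (grepl("[.]csv$", path, ignore.case = TRUE)) readr::read_csv else readr::read_tsv
  raw <- reader(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(unname(col_map), names(raw))
  if (length(missing_cols)) {
    cli::cli_abort("Input file lacks column{?s} {.field {missing_cols}} named in {.arg col_map}.")
  }
  out <- raw[, unname(col_map), drop = FALSE]
  names(out) <- names(col_map)
  tibble::as_tibble(out)
}

#' Default ChEMBL column mapping
#'
#' @return Named character vector: standard field name -> ChEMBL column name.
#' @export
chembl_col_map <- function() {
  c(
    compound_id = "molecule_chembl_id",
    smiles = "canonical_smiles",
    target_id = "target_chembl_id",
    standard_type = "standard_type",
    standard_relation = "standard_relation",
    standard_value = "standard_value",
    standard_units = "standard_units",
    assay_confidence = "confidence_score",
    target_relationship = "relationship_type",
    organism = "target_organism"
  )
}

#' Write a curated activity class to TSV
#'
#' @param compounds Curated class tibble from [curate_activity_class()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_curated_class <- function(compounds, path) {
  readr::write_tsv(compounds, path, progress = FALSE)
  invisible(path)
}

#' Read a curated activity class from TSV
#'
#' @param path File written by [write_curated_class()] (or any delimited
#'   table with `compound_id`, `smiles` and `pki` columns).
#' @return Curated class tibble.
#' @export
read_curated_class <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(c("compound_id", "smiles", "pki"), names(out))
  if (length(missing_cols)) {
    cli::cli_abort("Curated class file lacks column{?s} {.field {missing_cols}}.")
  }
  out$compound_id <- as.character(out$compound_id)
  out
}
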