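# Synthetic analog-series generator with exact ground truth.
#
# Fixtures emulate the structure of real analog series: rigid fused-ring
# scaffolds decorated with a substituent set at a single attachment site,
# pKi values planted in two bands (a "potent" band offset by 2.6-2.9 pKi
# units and a "weak" band spread over 0.4 units) so that every
# potent/weak member pair is a cliff and no other pair is. Structurally
# analogous scaffold pairs are planted by decorating the same fused-ring
# template with two different small groups at a second, symmetry-distinct
# site, which makes the two series cores a core-MMP by construction.
# Substituent sets of paired scaffolds are kept disjoint so no
# cross-series MMPs arise; the substituent library is chosen so that no
# two substituents share a common sub-fragment core (no accidental
# series at secondary cut sites). Ground truth for every pipeline stage
# follows by construction.

scaffold_templates <- function() {
  c(
    anthracene       = "c1c%sc2cc3cc%sccc3cc2cc1",
    phenanthrene     = "c1cc%sc2ccc3cc%sccc3c2c1",
    acridine         = "c1c%scc2nc3c%scccc3cc2c1",
    dibenzofuran     = "c1c%sccc2c1oc1c2cc%scc1",
    carbazole        = "c1c%sccc2c1[nH]c1c2cc%scc1",
    dibenzothiophene = "c1c%sccc2c1sc1c2cc%scc1",
    fluorene         = "c1c%sccc2c1Cc1c2cc%scc1",
    xanthene         = "c1c%sccc2c1Cc1c%scccc1O2",
    dibenzodioxin    = "c1c%sccc2c1Oc1c%scccc1O2",
    phenazine        = "c1c%scc2nc3c%scccc3nc2c1",
    chromenone       = "c1c%sccc2c1oc(=O)c1cc%sccc21",
    anthraquinone    = "c1c%sccc2c1C(=O)c1c%scccc1C2=O"
  )
}

substituent_library <- function() {
  tibble::tibble(
    smiles = c(
      "C", "F", "Cl", "Br", "I", "O", "N",
      "CC", "C#N", "OC", "N(C)C", "C(F)(F)F", "S(C)(=O)=O",
      "c8ccccc8", "c8ccncc8", "c8ccoc8", "c8cccs8"
    ),
    heavy = c(1L, 1L, 1L, 1L, 1L, 1L, 1L, 2L, 2L, 2L, 3L, 4L, 4L, 6L, 6L, 5L, 5L)
  )
}

decoration_pair <- function() c("(Cl)", "(C)")

#' Specify a synthetic analog-series fixture
#'
#' @param n_scaffolds Number of analog series (scaffolds) to generate.
#' @param substituents_per_scaffold Substituents (= compounds) per
#'   scaffold; a single value or a vector recycled across scaffolds.
#'   Scaffolds belonging to an analogous pair draw disjoint substituent
#'   sets, so paired scaffolds support at most half the library.
#' @param n_analog_pairs Number of planted analogous scaffold pairs
#'   (each pair consumes two scaffolds built on one fused-ring template
#'   with two different decorations).
#' @param potent_per_scaffold Number of members per scaffold placed in
#'   the potent pKi band; a value, a vector, or `NULL` to draw randomly
#'   (0 to all members). Planted intra-series cliff count per scaffold is
#'   `potent * (members - potent)`.
#' @param seed Integer seed; identical specs and seeds generate
#'   byte-identical fixtures.
#' @return A `fixture_spec` object.
#' @export
fixture_spec <- function(n_scaffolds = 6L,
                         substituents_per_scaffold = 4L,
                         n_analog_pairs = 2L,
                         potent_per_scaffold = NULL,
                         seed = 1L) {
  n_scaffolds <- as.integer(n_scaffolds)
  n_analog_pairs <- as.integer(n_analog_pairs)
  n_templates <- length(scaffold_templates())
  n_lib <- nrow(substituent_library())
  if (n_scaffolds < 1L) cli::cli_abort("Need at least one scaffold.")
  if (n_analog_pairs < 0L || 2L * n_analog_pairs > n_scaffolds) {
    cli::cli_abort("{.arg n_analog_pairs} must satisfy 0 <= 2 * pairs <= n_scaffolds.")
  }
  templates_needed <- n_analog_pairs + (n_scaffolds - 2L * n_analog_pairs)
  if (templates_needed > n_templates) {
    cli::cli_abort(
      "Spec needs {templates_needed} scaffold templates but only {n_templates} are available."
    )
  }
  k <- as.integer(rep_len(substituents_per_scaffold, n_scaffolds))
  if (any(k < 2L)) cli::cli_abort("Each scaffold needs at least 2 substituents.")
  paired <- rep(FALSE, n_scaffolds)
  if (n_analog_pairs > 0L) paired[seq_len(2L * n_analog_pairs)] <- TRUE
  if (n_analog_pairs > 0L) {
    pair_idx <- matrix(seq_len(2L * n_analog_pairs), nrow = 2L)
    pair_load <- k[pair_idx[1L, ]] + k[pair_idx[2L, ]]
    if (any(pair_load > n_lib)) {
      cli::cli_abort(
        "An analogous pair requests more substituents than the library holds ({n_lib})."
      )
    }
  }
  if (any(k[!paired] > n_lib)) {
    cli::cli_abort("A scaffold requests more substituents than the library holds ({n_lib}).")
  }
  if (!is.null(potent_per_scaffold)) {
    h <- as.integer(rep_len(potent_per_scaffold, n_scaffolds))
    if (any(h < 0L) || any(h > k)) {
      cli::cli_abort("{.arg potent_per_scaffold} must lie in [0, members] per scaffold.")
    }
  } else {
    h <- NULL
  }
  structure(
    list(
      n_scaffolds = n_scaffolds,
      substituents_per_scaffold = k,
      n_analog_pairs = n_analog_pairs,
      potent_per_scaffold = h,
      seed = as.integer(seed)
    ),
    class = "fixture_spec"
  )
}

#' Generate a synthetic analog-series fixture with ground truth
#'
#' Builds compounds by attaching substituents to fused-ring scaffolds
#' and planting pKi values in two bands, then derives the expected
#' result of every pipeline stage by construction: MMP pairs, cliff
#' pairs, AC compounds, series memberships and series-pair relations.
#'
#' @param spec A [fixture_spec()].
#' @return An `ac_fixture`: list with `compounds` (tibble: `compound_id`,
#'   `smiles`, `pki`, `scaffold_id`, `substituent`, `potent`), `truth`
#'   (list: `mmp_pairs`, `cliff_pairs`, `ac_ids`, `mms` — named list of
#'   member-id vectors per series-forming scaffold, `mmsp_pairs` —
#'   tibble of scaffold pairs, and `counts`), and `spec`.
#' @examples
#' fx <- generate_fixture(fixture_spec(n_scaffolds = 2, seed = 7))
#' fx$truth$counts
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  withr::with_seed(spec$seed, generate_fixture_impl(spec))
}

generate_fixture_impl <- function(spec) {
  tpl <- scaffold_templates()
  lib <- substituent_library()
  deco <- decoration_pair()
  n <- spec$n_scaffolds
  k <- spec$substituents_per_scaffold
  npair <- spec$n_analog_pairs

  template_order <- sample(names(tpl))
  scaffolds <- tibble::tibble(
    scaffold_id = sprintf("S%02d", seq_len(n)),
    template = NA_character_,
    decoration = "",
    pair_id = NA_integer_,
    n_members = k
  )
  ti <- 1L
  if (npair > 0L) {
    for (p in seq_len(npair)) {
      i <- 2L * p - 1L
      scaffolds$template[c(i, i + 1L)] <- template_order[ti]
      scaffolds$decoration[c(i, i + 1L)] <- deco
      scaffolds$pair_id[c(i, i + 1L)] <- p
      ti <- ti + 1L
    }
  }
  for (i in seq_len(n)) {
    if (is.na(scaffolds$template[i])) {
      scaffolds$template[i] <- template_order[ti]
      ti <- ti + 1L
    }
  }

  # substituent assignment: disjoint sets within an analogous pair
  sub_sets <- vector("list", n)
  for (p in seq_len(npair)) {
    i <- 2L * p - 1L
    picked <- sample(nrow(lib), k[i] + k[i + 1L])
    sub_sets[[i]] <- picked[seq_len(k[i])]
    sub_sets[[i + 1L]] <- picked[k[i] + seq_len(k[i + 1L])]
  }
  for (i in seq_len(n)) {
    if (is.null(sub_sets[[i]])) sub_sets[[i]] <- sample(nrow(lib), k[i])
  }

  h <- spec$potent_per_scaffold
  if (is.null(h)) h <- vapply(k, function(m) sample(0:m, 1L), integer(1))

  rows <- list()
  cpd_counter <- 0L
  for (i in seq_len(n)) {
    subs <- lib[sub_sets[[i]], , drop = FALSE]
    base <- stats::runif(1L, 4.5, 7.0)
    potent <- rep(FALSE, k[i])
    if (h[i] > 0L) potent[sample(k[i], h[i])] <- TRUE
    offset <- ifelse(potent, stats::runif(k[i], 2.6, 2.9), stats::runif(k[i], 0, 0.4))
    ids <- sprintf("CPD%04d", cpd_counter + seq_len(k[i]))
    cpd_counter <- cpd_counter + k[i]
    rows[[i]] <- tibble::tibble(
      compound_id = ids,
      smiles = sprintf(
        tpl[[scaffolds$template[i]]],
        paste0("(", subs$smiles, ")"),
        scaffolds$decoration[i]
      ),
      pki = round(base + offset, 3L),
      scaffold_id = scaffolds$scaffold_id[i],
      substituent = subs$smiles,
      potent = potent
    )
  }
  compounds <- dplyr::bind_rows(rows)

  truth <- derive_truth(compounds, scaffolds)
  structure(
    list(compounds = compounds, truth = truth, spec = spec, scaffolds = scaffolds),
    class = "ac_fixture"
  )
}

derive_truth <- function(compounds, scaffolds) {
  by_scaffold <- split(compounds, compounds$scaffold_id)
  mmp <- list()
  cliff <- list()
  for (sc in names(by_scaffold)) {
    m <- by_scaffold[[sc]]
    if (nrow(m) < 2L) next
    pr <- utils::combn(sort(m$compound_id, method = "radix"), 2L)
    mmp[[sc]] <- tibble::tibble(compound_a = pr[1L, ], compound_b = pr[2L, ])
    pki <- stats::setNames(m$pki, m$compound_id)
    d <- abs(pki[pr[1L, ]] - pki[pr[2L, ]])
    is_cliff <- d >= 2.0
    if (any(is_cliff)) {
      cliff[[sc]] <- tibble::tibble(
        compound_a = pr[1L, is_cliff], compound_b = pr[2L, is_cliff]
      )
    }
  }
  mmp_pairs <- dplyr::bind_rows(mmp)
  cliff_pairs <- if (length(cliff)) dplyr::bind_rows(cliff) else {
    tibble::tibble(compound_a = character(0), compound_b = character(0))
  }
  ac_ids <- sort(unique(c(cliff_pairs$compound_a, cliff_pairs$compound_b)), method = "radix")

  mms <- list()
  for (sc in names(by_scaffold)) {
    members <- intersect(by_scaffold[[sc]]$compound_id, ac_ids)
    if (length(members) >= 2L) mms[[sc]] <- sort(members, method = "radix")
  }

  mmsp <- list()
  paired <- scaffolds[!is.na(scaffolds$pair_id), , drop = FALSE]
  for (p in unique(paired$pair_id)) {
    sids <- paired$scaffold_id[paired$pair_id == p]
    if (all(sids %in% names(mms))) {
      mmsp[[length(mmsp) + 1L]] <- tibble::tibble(
        scaffold_a = min(sids), scaffold_b = max(sids)
      )
    }
  }
  mmsp_pairs <- if (length(mmsp)) dplyr::bind_rows(mmsp) else {
    tibble::tibble(scaffold_a = character(0), scaffold_b = character(0))
  }

  list(
    mmp_pairs = dplyr::arrange(mmp_pairs, .data$compound_a, .data$compound_b),
    cliff_pairs = dplyr::arrange(cliff_pairs, .data$compound_a, .data$compound_b),
    ac_ids = ac_ids,
    mms = mms,
    mmsp_pairs = mmsp_pairs,
    counts = list(
      n_compounds = nrow(compounds),
      n_mmps = nrow(mmp_pairs),
      n_cliffs = nrow(cliff_pairs),
      n_ac_compounds = length(ac_ids),
      n_mms = length(mms),
      n_mmsps = nrow(mmsp_pairs)
    )
  )
}

#' @export
print.ac_fixture <- function(x, ...) {
  cat(sprintf(
    "Synthetic fixture (seed %d): %d compounds on %d scaffolds; truth: %d MMPs, %d cliffs, %d MMSs, %d MMSPs\n",
    x$spec$seed, nrow(x$compounds), x$spec$n_scaffolds,
    x$truth$counts$n_mmps, x$truth$counts$n_cliffs,
    x$truth$counts$n_mms, x$truth$counts$n_mmsps
  ))
  invisible(x)
}

#' Write a fixture to disk
#'
#' Writes the curated-class TSV consumed by the pipeline and the ground
#' truth as JSON.
#'
#' @param fixture An `ac_fixture` from [generate_fixture()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_curated_class(
    fixture$compounds[, c("compound_id", "smiles", "pki")],
    file.path(dir, "compounds.tsv")
  )
  jsonlite::write_json(
    fixture$truth,
    file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}
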