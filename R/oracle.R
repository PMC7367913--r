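# Brute-force all-pairs MMP detection: the reference method used to
# validate the indexed enumeration and to guard generated fixtures
# against unplanned structural matches. Deliberately quadratic: every
# compound pair is tested directly for a shared single-cut decomposition
# under the size rules, with no core indexing or pair deduplication
# logic.

#' Brute-force matched molecular pair detection
#'
#' For every pair of compounds, fragments both and tests directly
#' whether any single-cut decomposition matches: a shared core (same
#' molecule, same substitution site) with distinct substituents whose
#' size difference is within `max_exchange_diff`. Intended for
#' validation at small scale; use [enumerate_mmps()] for real work.
#'
#' @param compounds Data frame with `compound_id` and `smiles`.
#' @param rules A [size_rules()] object.
#' @return Tibble of unordered MMP pairs: `compound_a`, `compound_b`
#'   (`compound_a < compound_b`).
#' @export
brute_force_mmps <- function(compounds, rules = size_rules()) {
  rules <- as_size_rules(rules)
  ids <- sort(as.character(compounds$compound_id), method = "radix")
  compounds <- compounds[match(ids, compounds$compound_id), , drop = FALSE]
  frags <- lapply(seq_len(nrow(compounds)), function(i) {
    fragment_compounds(compounds[i, , drop = FALSE], rules = rules)
  })
  out <- list()
  n <- length(ids)
  for (i in seq_len(n - 1L)) {
    fi <- frags[[i]]
    if (!nrow(fi)) next
    for (j in (i + 1L):n) {
      fj <- frags[[j]]
      if (!nrow(fj)) next
      hit <- FALSE
      for (ci in seq_len(nrow(fi))) {
        match_rows <- which(fj$core_key == fi$core_key[ci])
        for (cj in match_rows) {
          if (fj$substituent_key[cj] != fi$substituent_key[ci] &&
              abs(fj$sub_heavy[cj] - fi$sub_heavy[ci]) <= rules$max_exchange_diff) {
            hit <- TRUE
            break
          }
        }
        if (hit) break
      }
      if (hit) {
        out[[length(out) + 1L]] <- tibble::tibble(
          compound_a = ids[i], compound_b = ids[j]
        )
      }
    }
  }
  if (!length(out)) {
    return(tibble::tibble(compound_a = character(0), compound_b = character(0)))
  }
  dplyr::bind_rows(out)
}

#' Check a fixture for unplanned structural matches
#'
#' Runs [brute_force_mmps()] over a generated fixture and returns any
#' MMP pairs not present in its planted truth. The scaffold and
#' substituent libraries are designed so that this set is empty; if
#' matches do arise they should be added to the truth rather than
#' ignored.
#'
#' @param fixture An `ac_fixture` from [generate_fixture()].
#' @param rules A [size_rules()] object.
#' @return Tibble of unplanned pairs (zero rows when the fixture is clean).
#' @export
unplanned_mmps <- function(fixture, rules = size_rules()) {
  found <- brute_force_mmps(fixture$compounds, rules = rules)
  dplyr::anti_join(
    found, fixture$truth$mmp_pairs,
    by = c("compound_a", "compound_b")
  )
}
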