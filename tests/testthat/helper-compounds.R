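# Small in-code fixtures shared across test files.

# A minimal analog series on a benzene core: methyl / ethyl / propyl,
# with pKi values planting exactly two cliffs (5.0/7.5 and 5.1/7.5).
mini_series <- function() {
  tibble::tibble(
    compound_id = c("tol", "eb", "pb"),
    smiles = c("Cc1ccccc1", "CCc1ccccc1", "CCCc1ccccc1"),
    pki = c(5.0, 5.1, 7.5)
  )
}

# Unordered id pair tibble from a cliff table, sorted for comparison.
cliff_pairs_of <- function(cliffs) {
  dplyr::arrange(
    tibble::tibble(
      compound_a = pmin(cliffs$high_id, cliffs$low_id),
      compound_b = pmax(cliffs$high_id, cliffs$low_id)
    ),
    compound_a, compound_b
  )
}

mmp_pairs_of <- function(mmps) {
  dplyr::arrange(
    mmps[, c("compound_a", "compound_b")],
    compound_a, compound_b
  )
}

# Canonical member-set signatures of an MMS table / truth list.
mms_signatures <- function(members_list) {
  sort(vapply(
    members_list,
    function(m) {
      ids <- if (is.data.frame(m)) m$compound_id else m
      paste(sort(unique(ids), method = "radix"), collapse = ",")
    },
    character(1)
  ), method = "radix")
}

# Hand-written alternative SMILES spellings of the same molecules, for
# canonicalization-invariance checks.
respellings <- function() {
  list(
    toluene = c("Cc1ccccc1", "c1ccccc1C", "C1=CC=CC=C1C", "c1ccc(C)cc1"),
    anisole = c("COc1ccccc1", "c1ccccc1OC", "O(C)c1ccccc1"),
    amide = c("CC(=O)Nc1ccccc1", "c1ccccc1NC(C)=O", "O=C(C)Nc1ccccc1")
  )
}
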