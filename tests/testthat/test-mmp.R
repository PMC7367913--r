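test_that("shared-core indexing finds the expected MMPs", {
  frags <- fragment_compounds(mini_series())
  mmps <- enumerate_mmps(frags)
  # all three pairs of {methyl, ethyl, propyl}benzene are MMPs
  expect_equal(nrow(mmps), 3)
  # tol pairs via the benzene core; the ethyl/propyl pair retains its
  # largest shared core (the 7-atom methylbenzene core, i.e. the
  # smallest transformation methyl -> ethyl)
  benzene <- canonical_smiles("c1ccccc1")
  toluene <- canonical_smiles("Cc1ccccc1")
  expect_equal(
    sort(mmps$core_smiles),
    sort(c(benzene, benzene, toluene))
  )
  eb_pb <- mmps[mmps$compound_a == "eb" & mmps$compound_b == "pb", ]
  expect_equal(eb_pb$core_smiles, toluene)
  expect_equal(eb_pb$exchange_diff, 1L)
  tol_eb <- mmps[mmps$compound_a == "eb" & mmps$compound_b == "tol", ]
  expect_equal(nrow(tol_eb), 1)
  expect_equal(tol_eb$exchange_diff, 1L)
  expect_setequal(c(tol_eb$substituent_a, tol_eb$substituent_b), c("*C", "*CC"))
})

test_that("a compound never pairs with itself and identical substituents never pair", {
  dup <- tibble::tibble(
    compound_id = c("a", "b"),
    smiles = c("Cc1ccccc1", "Cc1ccccc1") # same structure, two ids
  )
  mmps <- enumerate_mmps(fragment_compounds(dup))
  expect_equal(nrow(mmps), 0)
})

test_that("the exchange-size rule excludes oversized transformations", {
  # decyl vs methyl on a large core: substituent size difference 9 > 8
  cmpds <- tibble::tibble(
    compound_id = c("small", "large"),
    smiles = c(
      "Cc1ccc2cc3cc(C)ccc3cc2c1",
      "CCCCCCCCCCc1ccc2cc3cc(C)ccc3cc2c1"
    )
  )
  frags <- fragment_compounds(cmpds, size_rules(max_sub_heavy = 13))
  mmps <- enumerate_mmps(frags)
  expect_false(any(mmps$exchange_diff > 8))
  # the methyl<->decyl exchange itself must be absent
  expect_false(any(
    (mmps$substituent_a == "*C" & nchar(mmps$substituent_b) > 10) |
      (mmps$substituent_b == "*C" & nchar(mmps$substituent_a) > 10)
  ))
})

test_that("multi-core pairs are reported once with the largest core", {
  # anthracenyl-CH2-OH vs anthracenyl-CH2-Cl share two cores: the
  # benzylic core (exchange O/Cl) and the bare ring system (exchange
  # CH2OH/CH2Cl); the pair must appear exactly once
  cmpds <- tibble::tibble(
    compound_id = c("dpe", "dpt"),
    smiles = c("OCc1ccc2cc3ccccc3cc2c1", "ClCc1ccc2cc3ccccc3cc2c1")
  )
  mmps <- enumerate_mmps(fragment_compounds(cmpds))
  expect_equal(nrow(mmps), 1)
  # retained representative is the largest shared core (smallest exchange)
  frags <- fragment_compounds(cmpds)
  shared <- intersect(
    frags$core_key[frags$compound_id == "dpe"],
    frags$core_key[frags$compound_id == "dpt"]
  )
  biggest <- max(frags$core_heavy[frags$core_key %in% shared])
  expect_equal(mmps$core_heavy, biggest)
})

test_that("cliff detection applies the closed threshold and orients pairs", {
  cmpds <- mini_series() # pKi 5.0 / 5.1 / 7.5
  mmps <- enumerate_mmps(fragment_compounds(cmpds))
  cliffs <- detect_cliffs(mmps, cmpds)
  expect_equal(nrow(cliffs), 2)
  expect_true(all(cliffs$high_id == "pb"))
  expect_true(all(cliffs$delta_pki >= 2))
  expect_true(all(cliffs$pki_high > cliffs$pki_low))

  # 1.9 misses, exactly 2.0 qualifies (closed inequality)
  near <- cmpds
  near$pki <- c(5.0, 6.9, 7.0)
  cl <- detect_cliffs(mmps, near)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$delta_pki, 2.0)
  expect_equal(cl$high_id, "pb")
  expect_equal(cl$low_id, "tol")
})

test_that("missing potency values fail loudly", {
  cmpds <- mini_series()
  mmps <- enumerate_mmps(fragment_compounds(cmpds))
  expect_error(detect_cliffs(mmps, cmpds[-1, ]), "tol")
})

test_that("cliffs are a subset of MMPs and thresholds act monotonically", {
  fx <- generate_fixture(fixture_spec(n_scaffolds = 3, substituents_per_scaffold = 5,
                                      n_analog_pairs = 1, seed = 5))
  frags <- fragment_compounds(fx$compounds)
  mmps <- enumerate_mmps(frags)
  cliffs <- detect_cliffs(mmps, fx$compounds)
  expect_true(all(
    acnet:::pair_key(cliffs$high_id, cliffs$low_id) %in%
      acnet:::pair_key(mmps$compound_a, mmps$compound_b)
  ))
  # raising the cliff threshold never adds cliffs
  stricter <- detect_cliffs(mmps, fx$compounds, size_rules(min_delta_pki = 2.5))
  expect_lte(nrow(stricter), nrow(cliffs))
  expect_true(all(
    acnet:::pair_key(stricter$high_id, stricter$low_id) %in%
      acnet:::pair_key(cliffs$high_id, cliffs$low_id)
  ))
  # relaxing max_sub_heavy never removes MMPs
  frags_wide <- fragment_compounds(fx$compounds, size_rules(max_sub_heavy = 20))
  mmps_wide <- enumerate_mmps(frags_wide, size_rules(max_sub_heavy = 20))
  expect_true(all(
    acnet:::pair_key(mmps$compound_a, mmps$compound_b) %in%
      acnet:::pair_key(mmps_wide$compound_a, mmps_wide$compound_b)
  ))
})

test_that("indexed enumeration equals the brute-force all-pairs oracle", {
  fx <- generate_fixture(fixture_spec(n_scaffolds = 4, substituents_per_scaffold = 4,
                                      n_analog_pairs = 2, seed = 13))
  # add a few unrelated small molecules to exercise non-matching pairs
  extra <- tibble::tibble(
    compound_id = c("x1", "x2", "x3"),
    smiles = c("CC(=O)Nc1ccc(O)cc1", "CC(=O)Nc1ccc(OC)cc1", "c1ccc2[nH]ccc2c1"),
    pki = c(5, 6, 7), scaffold_id = "X", substituent = NA, potent = FALSE
  )
  cmpds <- dplyr::bind_rows(fx$compounds, extra)
  indexed <- mmp_pairs_of(enumerate_mmps(fragment_compounds(cmpds)))
  brute <- dplyr::arrange(brute_force_mmps(cmpds), compound_a, compound_b)
  expect_identical(indexed, brute)
  # the unrelated paracetamol analogs do pair with each other only
  expect_true(nrow(dplyr::filter(brute, compound_a == "x1", compound_b == "x2")) == 1)
  expect_false(any(brute$compound_a == "x3" | brute$compound_b == "x3"))
})
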