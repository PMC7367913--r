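test_that("single-cut enumeration matches manual expectations", {
  # toluene: one acyclic heavy-heavy single bond; benzene core + methyl
  tol <- enumerate_cuts("Cc1ccccc1")
  expect_equal(nrow(tol), 1)
  expect_equal(tol$core_smiles, canonical_smiles("c1ccccc1"))
  expect_equal(tol$core_heavy, 6L)
  expect_equal(tol$sub_heavy, 1L)

  # benzene: no acyclic bonds at all
  expect_equal(nrow(enumerate_cuts("c1ccccc1")), 0)

  # n-pentylbenzene: 5 acyclic C-C bonds, but substituents of 4 or 5
  # heavy atoms fail the 2:1 core/substituent ratio -> 3 records
  pb <- enumerate_cuts("CCCCCc1ccccc1")
  expect_equal(nrow(pb), 3)
  expect_true(all(pb$core_heavy >= 2 * pb$sub_heavy))
  expect_true(all(pb$sub_heavy <= 3))
})

test_that("size rules restrict cuts as configured", {
  # with a laxer ratio, the pentylbenzene mid-chain cuts qualify too
  lax <- enumerate_cuts("CCCCCc1ccccc1", size_rules(core_to_sub_ratio = 1))
  expect_gt(nrow(lax), 3)
  # hexane under ratio 1: cuts at both chain ends and the symmetric
  # middle collapse to three unique (core, substituent) records
  hex <- enumerate_cuts("CCCCCC", size_rules(core_to_sub_ratio = 1))
  expect_equal(nrow(hex), 3)
  expect_setequal(hex$sub_heavy, 1:3)
  # max_sub_heavy caps substituent size
  tight <- enumerate_cuts("CCCCCc1ccccc1", size_rules(max_sub_heavy = 1))
  expect_true(all(tight$sub_heavy == 1))
})

test_that("ring bonds are never cut and charges survive fragmentation", {
  # biphenyl: single acyclic bond between the rings fails the ratio rule
  # (6 vs 6), so no record under defaults but two under ratio 1
  expect_equal(nrow(enumerate_cuts("c1ccccc1-c1ccccc1")), 0)
  expect_equal(nrow(enumerate_cuts("c1ccccc1-c1ccccc1", size_rules(core_to_sub_ratio = 1))), 1)

  # charged compound: fragment SMILES keep the charge annotation
  frag <- enumerate_cuts("[O-]C(=O)c1ccccc1CC[NH3+]")
  expect_true(any(grepl("NH3", frag$substituent_key) | grepl("NH3", frag$core_smiles)))
})

test_that("core and substituent heavy atoms sum to the parent count", {
  mols <- c(
    "Cc1ccccc1", "CCc1ccccc1", "CCCCCc1ccccc1", "COc1cc2c(cc1OC)CCN2",
    "CC(=O)Nc1ccc(O)cc1", "Clc1ccc2nc3ccccc3cc2c1"
  )
  for (m in mols) {
    frag <- enumerate_cuts(m)
    if (!nrow(frag)) next
    g <- acnet:::mol_graphs(c(x = canonical_smiles(m)))[["x"]]
    n_heavy <- length(acnet:::heavy_atoms(g))
    expect_true(all(frag$core_heavy + frag$sub_heavy == n_heavy), label = m)
  }
})

test_that("reattaching the substituent reproduces the parent molecule", {
  mols <- c(
    "Cc1ccccc1", "CCCCCc1ccccc1", "CC(=O)Nc1ccc(O)cc1",
    "COc1cc2c(cc1OC)CCN2", "Cc1ccc2nc3ccccc3cc2c1"
  )
  for (m in mols) {
    can <- canonical_smiles(m)
    frag <- enumerate_cuts(m)
    if (!nrow(frag)) next
    rebuilt <- attach_substituent(frag$core_key, frag$substituent_key)
    expect_equal(rebuilt, rep(can, nrow(frag)), label = m)
  }
})

test_that("fragmentation is invariant under SMILES respelling", {
  for (variants in respellings()) {
    records <- lapply(variants, function(v) {
      out <- enumerate_cuts(v)
      out$compound_id <- NULL
      dplyr::arrange(out, core_key, substituent_key)
    })
    for (i in seq_along(records)[-1]) {
      expect_identical(records[[i]], records[[1]])
    }
  }
})

test_that("core identity collapses symmetry-equivalent sites and separates others", {
  # toluene and ethylbenzene cores: benzene substituted anywhere is one key
  k1 <- enumerate_cuts("Cc1ccccc1")$core_key
  k2 <- enumerate_cuts("CCc1ccccc1")$core_key
  expect_true(k1 %in% k2)

  # ortho vs para substituted phenol cores differ
  ortho <- enumerate_cuts("Cc1ccccc1O")
  para <- enumerate_cuts("Cc1ccc(O)cc1")
  k_ortho <- ortho$core_key[ortho$substituent_key == "*C"]
  k_para <- para$core_key[para$substituent_key == "*C"]
  expect_false(any(k_ortho %in% k_para))
})

test_that("strict exocyclic mode drops cuts without a ring-atom terminus", {
  # ethylbenzene: the terminal C-C bond touches no ring atom, the
  # chain-ring bond does
  all_cuts <- enumerate_cuts("CCc1ccccc1")
  exo <- enumerate_cuts("CCc1ccccc1", mode = "exocyclic")
  expect_equal(nrow(all_cuts), 2)
  expect_equal(nrow(exo), 1)
  expect_equal(exo$sub_heavy, 2L)
})

test_that("unparseable structures fail with the compound named", {
  expect_error(
    suppressWarnings(
      fragment_compounds(tibble::tibble(compound_id = "bad1", smiles = "xyz"))
    ),
    "bad1"
  )
})
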