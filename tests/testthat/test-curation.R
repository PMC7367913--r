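test_that("pKi conversion follows the molar definition", {
  expect_equal(to_pki(1), 9)
  expect_equal(to_pki(100), 7)
  expect_equal(to_pki(223872), 3.65, tolerance = 0.005 / 3.65)
  expect_error(to_pki(0), "positive")
  expect_error(to_pki(-5), "positive")
})

test_that("record filtering applies every selection rule and preserves order", {
  base <- tibble::tibble(
    compound_id = sprintf("c%d", 1:8),
    smiles = "Cc1ccccc1",
    target_id = "T1",
    standard_type = "Ki",
    standard_relation = "=",
    standard_value = "10",
    standard_units = "nM",
    assay_confidence = 9L,
    target_relationship = "D",
    organism = "Homo sapiens"
  )
  recs <- base
  recs$standard_relation[2] <- "<"
  recs$assay_confidence[3] <- 8L
  recs$target_relationship[4] <- "H"
  recs$organism[5] <- "Rattus norvegicus"
  recs$standard_units[6] <- "uM"
  recs$standard_type[7] <- "IC50"
  out <- filter_activity_records(recs, "T1")
  expect_equal(out$compound_id, c("c1", "c8"))
  expect_type(out$standard_value, "double")

  # wrong target excluded entirely
  expect_equal(nrow(filter_activity_records(recs, "T2")), 0)
})

test_that("unparseable values are skipped with a warning, not silently", {
  recs <- tibble::tibble(
    compound_id = c("a", "b"),
    smiles = "Cc1ccccc1",
    target_id = "T1",
    standard_type = "Ki",
    standard_relation = "=",
    standard_value = c("12.5", "n.d."),
    standard_units = "nM",
    assay_confidence = 9L,
    target_relationship = "D",
    organism = "Homo sapiens"
  )
  expect_warning(out <- filter_activity_records(recs, "T1"), "unparseable")
  expect_equal(out$compound_id, "a")
})

test_that("consolidation averages consistent measurements and rejects inconsistent ones", {
  expect_equal(
    consolidate_compounds(data.frame(compound_id = "x", pki = 7.2))$pki, 7.2
  )
  out <- consolidate_compounds(data.frame(compound_id = "x", pki = c(6.0, 6.9)))
  expect_equal(out$pki, 6.45)
  expect_equal(out$n_measurements, 2L)
  # range 1.5 > 1.0: compound disregarded
  expect_equal(
    nrow(consolidate_compounds(data.frame(compound_id = "x", pki = c(6.0, 7.5)))),
    0
  )
  expect_error(consolidate_compounds(data.frame(compound_id = character(0), pki = numeric(0))))
})

test_that("consolidation is permutation-invariant and bounded by the measurements", {
  set.seed(42)
  for (i in 1:20) {
    vals <- round(runif(sample(2:5, 1), 5, 6), 3)
    a <- consolidate_compounds(data.frame(compound_id = "x", pki = vals))
    b <- consolidate_compounds(data.frame(compound_id = "x", pki = sample(vals)))
    expect_identical(a, b)
    if (nrow(a)) {
      expect_gte(a$pki, min(vals))
      expect_lte(a$pki, max(vals))
    }
  }
})

test_that("full curation standardizes structures and keeps ids unique", {
  recs <- tibble::tibble(
    compound_id = c("a", "a", "b", "c", "d"),
    smiles = c(
      "C1=CC=CC=C1C", "Cc1ccccc1",       # same molecule, two spellings
      "CCc1ccccc1.[Na+].[Cl-]",          # salt: keep largest fragment
      "not_a_smiles",                    # dropped with a warning
      "CCCc1ccccc1"
    ),
    target_id = "T1",
    standard_type = "Ki",
    standard_relation = "=",
    standard_value = c("10", "20", "100", "10", "1"),
    standard_units = "nM",
    assay_confidence = 9L,
    target_relationship = "D",
    organism = "Homo sapiens"
  )
  # two warnings: the parser reports the bad SMILES, curation reports the drop
  expect_warning(
    expect_warning(out <- curate_activity_class(recs, "T1"), "parse"),
    "parse"
  )
  expect_equal(sort(out$compound_id), c("a", "b", "d"))
  expect_false(any(duplicated(out$compound_id)))
  # salt stripped to the parent structure
  expect_equal(out$smiles[out$compound_id == "b"], canonical_smiles("CCc1ccccc1"))
  # a: mean of pKi(10 nM)=8 and pKi(20 nM)=log10 mean, on the pKi scale
  expect_equal(out$pki[out$compound_id == "a"], mean(9 - log10(c(10, 20))))
  # filtering then consolidating n records yields <= n compounds
  expect_lte(nrow(out), nrow(recs))
})

test_that("curated classes round-trip through TSV", {
  cur <- mini_series()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_curated_class(cur, path)
  back <- read_curated_class(path)
  expect_equal(back$compound_id, cur$compound_id)
  expect_equal(back$pki, cur$pki)
})
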