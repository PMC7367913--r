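make_cliffs <- function(pairs, pki) {
  # pairs: list of c(high, low); pki: named vector
  tibble::tibble(
    high_id = vapply(pairs, `[`, character(1), 1),
    low_id = vapply(pairs, `[`, character(1), 2),
    pki_high = pki[vapply(pairs, `[`, character(1), 1)],
    pki_low = pki[vapply(pairs, `[`, character(1), 2)],
    delta_pki = pki[vapply(pairs, `[`, character(1), 1)] -
      pki[vapply(pairs, `[`, character(1), 2)],
    core_key = "*c1ccccc1", core_smiles = "c1ccccc1",
    substituent_high = "*C", substituent_low = "*CC",
    exchange_diff = 1L
  )
}

test_that("a single cliff yields a minimal two-node network", {
  pki <- c(A = 8, B = 5)
  net <- build_ac_network(make_cliffs(list(c("A", "B")), pki),
    tibble::tibble(compound_id = names(pki), pki = unname(pki))
  )
  expect_equal(nrow(net$nodes), 2)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$nodes$role[net$nodes$compound_id == "A"], "high")
  expect_equal(net$nodes$role[net$nodes$compound_id == "B"], "low")
  expect_equal(length(unique(net$nodes$component)), 1)
  cc <- classify_cliffs(net)
  expect_equal(cc$n_isolated, 1)
  expect_equal(cc$n_coordinated, 0)
})

test_that("node roles distinguish consistently high, low and mixed compounds", {
  pki <- c(A = 7, B = 4.5, C = 9.5)
  # cliffs A>B and C>A: A is high in one, low in the other
  net <- build_ac_network(
    make_cliffs(list(c("A", "B"), c("C", "A")), pki),
    tibble::tibble(compound_id = names(pki), pki = unname(pki))
  )
  roles <- setNames(net$nodes$role, net$nodes$compound_id)
  expect_equal(roles[["A"]], "mixed")
  expect_equal(roles[["B"]], "low")
  expect_equal(roles[["C"]], "high")
  # role counts partition the AC compounds
  expect_equal(sum(table(net$nodes$role)), nrow(net$nodes))
})

test_that("triangles are coordinated and component edges are conserved", {
  pki <- c(A = 9, B = 6.5, C = 4, D = 9, E = 5)
  cliffs <- make_cliffs(list(c("A", "C"), c("B", "C"), c("A", "E"), c("D", "E")), pki)
  net <- build_ac_network(cliffs, tibble::tibble(compound_id = names(pki), pki = unname(pki)))
  cc <- classify_cliffs(net)
  expect_equal(cc$n_coordinated + cc$n_isolated, nrow(net$edges))
  expect_equal(cc$n_isolated, 0)
  cls <- ac_clusters(net)
  expect_equal(sum(cls$n_cliffs), nrow(cliffs))
  expect_equal(sum(cls$n_compounds), nrow(net$nodes))
})

test_that("the reduced network carries the three display attributes", {
  fx <- generate_fixture(fixture_spec(n_scaffolds = 4, substituents_per_scaffold = 4,
                                      n_analog_pairs = 1, potent_per_scaffold = 1, seed = 31))
  p <- run_ac_pipeline(fx$compounds)
  red <- p$reduced
  expect_s3_class(red, "reduced_network")
  expect_true(all(c("n_members", "max_pki", "ac_propensity") %in% names(red$nodes)))
  expect_equal(nrow(red$nodes), nrow(p$mms))
  expect_equal(nrow(red$edges), nrow(p$mmsps))
  expect_equal(red$n_singletons, sum(red$nodes$degree == 0))
  # reduced network is never larger than the AC network's compound count
  expect_lte(nrow(red$nodes), choose(nrow(p$network$nodes), 2))
  # no self edges
  expect_true(all(red$edges$mms_a != red$edges$mms_b))
})

test_that("cluster coverage is complete over reduced components and exact on splits", {
  # two disjoint series of two members each whose cliffs form one AC
  # component? no -- construct the documented half/half case instead:
  # one AC cluster whose two cliffs live in two disjoint series
  mms <- tibble::tibble(
    mms_id = c("M1", "M2"),
    core_key = c("*c1ccccc1", "*c1ccncc1"),
    core_smiles = c("c1ccccc1", "c1ccncc1"),
    n_members = c(2L, 2L),
    max_pki = c(8, 8),
    members = list(
      tibble::tibble(compound_id = c("A", "B"), substituent_key = c("*C", "*CC"),
                     sub_heavy = c(1L, 2L), pki = c(8, 5)),
      tibble::tibble(compound_id = c("B", "C"), substituent_key = c("*C", "*CC"),
                     sub_heavy = c(1L, 2L), pki = c(5, 8))
    ),
    n_intra_cliffs = c(1L, 1L),
    ac_propensity = c(100, 100)
  )
  pki <- c(A = 8, B = 5, C = 8)
  cliffs <- make_cliffs(list(c("A", "B"), c("C", "B")), pki)
  net <- build_ac_network(cliffs, tibble::tibble(compound_id = names(pki), pki = unname(pki)))
  red <- build_reduced_network(mms, tibble::tibble(
    mms_a = character(0), mms_b = character(0), meta_core_key = character(0),
    core_substituent_a = character(0), core_substituent_b = character(0),
    exchange_diff = integer(0)
  ))
  cov <- cluster_coverage(net, red)
  # one AC component, two reduced singleton components, each covering half
  expect_equal(nrow(cov), 2)
  expect_equal(sort(cov$coverage), c(0.5, 0.5))

  # full pipeline: union of reduced components always covers every cliff
  fx <- generate_fixture(fixture_spec(n_scaffolds = 3, substituents_per_scaffold = 5,
                                      n_analog_pairs = 1, potent_per_scaffold = 2, seed = 37))
  p <- run_ac_pipeline(fx$compounds)
  total <- p$coverage |>
    dplyr::group_by(ac_component) |>
    dplyr::summarise(covered = sum(n_covered))
  per_comp <- dplyr::count(p$network$edges, component, name = "n_cliffs")
  expect_true(all(total$covered >= per_comp$n_cliffs[match(total$ac_component, per_comp$component)]))
})

test_that("network summaries and tidy accessors are consistent", {
  fx <- generate_fixture(fixture_spec(n_scaffolds = 3, substituents_per_scaffold = 4,
                                      n_analog_pairs = 1, potent_per_scaffold = 1, seed = 41))
  p <- run_ac_pipeline(fx$compounds)
  g <- glance(p$network)
  expect_equal(g$n_cliffs, nrow(p$cliffs))
  expect_equal(g$n_coordinated + g$n_isolated, g$n_cliffs)
  expect_equal(nrow(tidy(p$network, "nodes")), g$n_compounds)
  gr <- glance(p$reduced)
  expect_equal(gr$n_mms, nrow(p$mms))
  expect_equal(gr$n_connected_mms + gr$n_singleton_mms, gr$n_mms)
  nodes <- tidy(p$reduced, "nodes")
  expect_true("member_ids" %in% names(nodes))
  expect_false("members" %in% names(nodes))
})

test_that("GraphML and SIF exports round-trip node and edge counts", {
  fx <- generate_fixture(fixture_spec(n_scaffolds = 3, substituents_per_scaffold = 4,
                                      n_analog_pairs = 1, potent_per_scaffold = 1, seed = 43))
  p <- run_ac_pipeline(fx$compounds)
  dir <- withr::local_tempdir()
  gml <- file.path(dir, "ac.graphml")
  write_network_graphml(p$network, gml)
  back <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(back), nrow(p$network$nodes))
  expect_equal(igraph::ecount(back), nrow(p$network$edges))
  expect_true("delta_pki" %in% igraph::edge_attr_names(back))

  paths <- write_network_sif(p$reduced, file.path(dir, "red"))
  sif <- readLines(paste0(file.path(dir, "red"), ".sif"))
  expect_equal(length(sif), nrow(p$mmsps) + p$reduced$n_singletons)
  nodes_csv <- readr::read_csv(paths[2], show_col_types = FALSE)
  expect_equal(nrow(nodes_csv), nrow(p$mms))
})

test_that("network plots build without error", {
  fx <- generate_fixture(fixture_spec(n_scaffolds = 3, substituents_per_scaffold = 4,
                                      n_analog_pairs = 1, potent_per_scaffold = 1, seed = 47))
  p <- run_ac_pipeline(fx$compounds)
  expect_s3_class(ggplot2::ggplot_build(autoplot(p$network)), "ggplot_built")
  expect_s3_class(ggplot2::ggplot_build(autoplot(p$reduced)), "ggplot_built")
})
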