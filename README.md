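# acnet

Activity cliff networks and their reduction to matching molecular series.

## The problem

Activity cliffs (ACs) are pairs of structurally analogous compounds with a
large potency difference against the same target. They concentrate
structure-activity relationship (SAR) information: a small chemical change
with a large potency effect points directly at an SAR determinant. Most ACs
are not isolated pairs but occur *coordinated* — many compounds participate
in multiple cliffs — which is naturally explored in a network whose nodes
are compounds and whose edges are cliffs. As these networks grow, their
densely connected clusters become impossible to interpret by eye.

`acnet` builds the compound-level AC network and a **reduced network** that
replaces the cluster structure with a higher-level organization: nodes are
matching molecular series (MMSs, analog series sharing a core) and edges are
MMS pairs (MMSPs, series whose cores are themselves structural analogs).
All AC information is retained — every cliff pair lies inside at least one
series — while the topology becomes simple enough to read, and any node or
edge can be expanded into a standard R-group table for medicinal-chemistry
analysis.

## Method

For compounds with consolidated potencies (pKi = −log10 Ki [M]):

1. **Curation** — ChEMBL-style records are filtered (direct human target
   "D", assay confidence 9, Ki with "=" relation in nM), converted to pKi,
   and averaged per compound provided all measurements fall within one
   order of magnitude; otherwise the compound is disregarded.
2. **Fragmentation** — each compound is cut systematically at every acyclic
   single bond between heavy atoms, giving a core (hydrogen-completed at
   the cut site) and a substituent. Size rules keep the decompositions
   analog-like: core ≥ 2 × substituent heavy atoms, substituent ≤ 13 heavy
   atoms.
3. **MMPs and cliffs** — two compounds sharing a core (same molecule, same
   substitution site) with distinct substituents differing by ≤ 8 heavy
   atoms form a matched molecular pair (MMP); an MMP with ΔpKi ≥ 2.0
   (≥ 100-fold in Ki) is an MMP-cliff. Each unordered pair is counted
   once, keeping the largest shared core.
4. **MMS / MMSP** — cores carried by ≥ 2 AC compounds define the series;
   a second round of fragmentation applied to the series cores identifies
   core-MMPs, i.e. structurally analogous series (MMSPs).
5. **Networks** — the AC network (compounds × cliffs, with high/low/mixed
   potency roles) and the reduced network (MMS nodes carrying member
   count, maximum pKi and AC propensity — the percentage of member pairs
   that are cliffs — with MMSP edges). Both export to GraphML and
   SIF + attribute CSVs for Cytoscape.

## Worked example

```r
library(acnet)
library(tibble)

compounds <- tibble(
  compound_id = c("tol", "eb", "pb"),
  smiles      = c("Cc1ccccc1", "CCc1ccccc1", "CCCc1ccccc1"),
  pki         = c(5.0, 5.1, 7.5)
)

frags  <- fragment_compounds(compounds)
mmps   <- enumerate_mmps(frags)
cliffs <- detect_cliffs(mmps, compounds)
cliffs[, c("high_id", "low_id", "delta_pki", "core_smiles")]
#>   high_id low_id delta_pki core_smiles
#> 1 pb      eb           2.4 Cc1ccccc1
#> 2 pb      tol          2.5 c1ccccc1
```

The propylbenzene/toluene pair is a cliff over the benzene core
(ΔpKi = 2.5); the propyl/ethyl pair pairs over its largest shared core,
methylbenzene, i.e. the smallest transformation (ethyl → methyl). The
three analogs form one benzene-core series whose AC propensity is
100 × 2/3 ≈ 66.7% (two of the three member pairs are cliffs):

```r
mms <- intra_mms_cliffs(extract_mms(frags, ac_compounds(cliffs), compounds), cliffs)
mms[, c("core_smiles", "n_members", "max_pki", "n_intra_cliffs", "ac_propensity")]
#>   core_smiles n_members max_pki n_intra_cliffs ac_propensity
#> 1 Cc1ccccc1           2     7.5              1         100
#> 2 c1ccccc1            3     7.5              2          66.7
```

A full run on a synthetic class with planted series (see
`generate_fixture()`) produces both networks and a manifest of all stage
counts:

```r
fx <- generate_fixture(fixture_spec(n_scaffolds = 6, substituents_per_scaffold = 5,
                                    n_analog_pairs = 2, potent_per_scaffold = 2, seed = 2))
p <- run_ac_pipeline(fx$compounds)
glance(p$reduced)
#>   n_mms n_mmsps n_connected_mms n_singleton_mms n_components mean_propensity
#> 1     6       2               4               2            4              60
```

Here 30 compounds forming 36 cliffs in 6 AC clusters reduce to 6 series
nodes, of which 4 are connected by the 2 planted series-pair relations
(cores differing by a Cl ↔ CH3 exchange) and 2 stand alone. R-group
tables for any series come from `mms_to_table()`; paired tables with the
core transformation from `mmsp_to_tables()`.

A command-line driver for the stage-by-stage pipeline is installed at
`inst/cli/acnet.R` (subcommands `run`, `curate`, `fragment`, `cliffs`,
`simulate`).

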