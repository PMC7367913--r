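---
title: "Reducing activity cliff networks to matching molecular series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reducing activity cliff networks to matching molecular series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acnet)
```

## The model

An activity cliff (AC) is a pair of structurally analogous compounds
with the same biological activity but a potency difference of at least
two orders of magnitude. `acnet` operationalizes "structurally
analogous" with the matched molecular pair (MMP) criterion: two
compounds qualify when a single-cut fragmentation decomposes both into
the *same core substituted at the same site*, exchanging one substituent
for another. This substructure-based criterion is deliberately strict —
it selects true analogs modified at a single site — which is what makes
the resulting networks chemically interpretable.

The pipeline is:

1. curation of raw activity records into one consolidated pKi per
   compound (pKi = −log10 of Ki in molar; for Ki in nM,
   pKi = 9 − log10 Ki);
2. systematic single-cut fragmentation of every acyclic single bond
   between heavy atoms, under size rules;
3. MMP enumeration by shared-core indexing and cliff detection at
   ΔpKi ≥ 2.0;
4. extraction of matching molecular series (MMSs) — cores carried by two
   or more AC compounds — and a second fragmentation round over the
   series cores to find core-MMPs, i.e. structurally analogous series
   (MMS pairs, MMSPs);
5. construction of the compound-level AC network (compounds × cliffs)
   and of the reduced network (MMS nodes × MMSP edges).

The reduction preserves all AC information by construction: both
partners of every cliff are AC compounds sharing the cliff's core, so
every cliff pair is contained in at least one series. The package
asserts this invariant on every run of its test suite.

## Tunable parameters

| Parameter | Default | Unit | Role |
|---|---|---|---|
| `core_to_sub_ratio` | 2 | — | core must have at least this multiple of the substituent's heavy atoms |
| `max_sub_heavy` | 13 | heavy atoms | largest substituent considered analog-like |
| `max_exchange_diff` | 8 | heavy atoms | largest size change in one exchange |
| `min_delta_pki` | 2.0 | pKi units | cliff threshold (100-fold in Ki) |
| `window` (curation) | 1.0 | pKi units | maximal spread among a compound's measurements |

The three size restrictions confine transformations to those typical of
analog series; with ratio 2 at most one orientation of any cut can
qualify as (core, substituent), so fragment records are unambiguous.
The cliff threshold uses a closed inequality (ΔpKi = 2.0 qualifies) and
comparisons are made on consolidated pKi values at full precision — no
rounding occurs before the comparison.

## Design decisions

Several choices were genuinely open and are worth recording.

**Averaging scale.** Multiple measurements are averaged on the pKi
scale (equivalently, the geometric mean of Ki). Potency spans orders of
magnitude, and downstream arithmetic (cliff detection) lives on the log
scale, so averaging there keeps the consolidation and the threshold
commensurable.

**"Same order of magnitude."** Consolidation accepts a compound when
the spread of its pKi values is at most 1.0 (a 10-fold Ki range). The
window is exposed as a parameter rather than hard-coded.

**Cut set.** "Single-cut fragmentation of exocyclic single bonds" is
implemented as all acyclic (non-ring) single bonds between heavy atoms —
the standard single-cut MMP scheme. A stricter mode
(`mode = "exocyclic"`) limits cuts to bonds with at least one ring-atom
terminus for users who prefer the literal reading.

**Attachment-site identity.** A core's identity is the canonical
SMILES of the core with a dummy atom (`*`) written at the substitution
site. Canonicalization makes the key invariant to input atom ordering
and collapses symmetry-equivalent sites (all positions of benzene are
one site), so identical analogs always share a core. The
hydrogen-completed core is carried alongside (`core_smiles`) for
display and reassembly; an explicit attachment-atom index is not needed
because the marker encodes it.

**Pair-level deduplication.** A compound pair reachable through
several cuts is one MMP — cliffs are edges, and edges must not be
double-counted. The representative kept is the largest shared core
(the smallest transformation), with lexicographic tie-breaks so output
is deterministic.

**Propensity counting.** The AC propensity of a series,
100 × (cliff pairs among members) / C(n, 2), counts a member pair only
if it appears in the class-level cliff set. A pair sharing the series
core could still fail the exchange-size rule; counting it would
disagree with the network's edges.

**Second-round site mapping.** Two series cores are analogous only if
their shared second-round core (meta-core) carries the original
substitution site at the same position; the meta-core key marks the
original site `[1*]` and the new cut site `[2*]`, and a cut whose
substituent side would swallow the original site is discarded. Without
this constraint, series substituted at unrelated positions of similar
scaffolds would be spuriously linked.

**Cluster counting.** "Cluster" means connected component in both
networks; no community detection is implied. Because an isolated cliff
is itself a two-node component, summaries report both conventions:
total components, and clusters proper (components with more than two
nodes) alongside the isolated-cliff count.

## The synthetic generator

`generate_fixture()` emulates what the pipeline is designed to find:
analog series (rigid fused-ring scaffolds, each decorated at one
attachment site with substituents from a built-in library) and
structurally analogous series (the same ring template carrying two
different small decorations at a second site, which makes the two
series cores a core-MMP by construction). pKi values are planted in two
bands — weak members within a 0.4-unit band, potent members offset by
2.6–2.9 units — so the intra-series cliff count is exactly
`potent × (members − potent)`, with no probabilistic boundary cases.

Three design constraints keep the planted truth exact rather than
approximate:

- the substituent library is prefix-free — no substituent is another's
  sub-fragment at the attachment side — so secondary cut sites never
  create unplanned shared cores;
- paired scaffolds draw disjoint substituent sets, so no cross-series
  MMPs arise;
- the two substitution sites of every template are symmetry-distinct
  (verified against canonical SMILES), so decorations cannot migrate
  between sites under canonicalization.

`unplanned_mmps()` re-checks a generated fixture against the
brute-force oracle; the test suite asserts the check comes back empty.

What the generator does *not* emulate: flexible linkers, multiple
substitution sites per compound, stereochemistry, measurement noise,
tautomerism, or the size distribution of real screening libraries.
Exact recovery of planted truth therefore demonstrates the
combinatorial correctness of the pipeline (indexing, deduplication,
grouping, graph construction), not robustness to the structural
standardization issues of real data, which enter through the curation
module and the underlying chemistry toolkit.

## Numerical and degenerate-input choices

- All SMILES handling (parsing, canonicalization, fragment round trips)
  goes through Open Babel; canonical strings are therefore
  toolkit-specific. Cross-toolkit agreement is tested at the level of
  the MMP *relation* against an independent RDKit oracle, where the two
  toolkits must agree pair for pair.
- A hard parse error in a batched conversion aborts Open Babel's
  remaining records; the wrapper retries stragglers one at a time so a
  single bad SMILES cannot silently drop later compounds.
- Fragment records are kekulized MOL blocks; implicit hydrogens
  complete the cut valences, which realizes hydrogen addition at the
  substitution site without explicit H bookkeeping.
- Stereochemistry is preserved in curated structures (stereoisomers
  remain distinct compounds) but is not encoded in fragment keys:
  fragment MOL blocks carry no stereo annotation, so two cores
  differing only in a stereocenter collapse. Multi-fragment inputs are
  desalted to the largest covalent component during curation.
- Degenerate inputs are handled explicitly: an empty curated class
  returns an empty manifest without error; a class with MMPs but no
  cliffs warns and produces empty networks with correctly typed empty
  tables; duplicate compound ids abort.

## Problem sizes

The test suite and the acceptance script work at desk scale: twenty
randomized fixtures of 6 to 192 compounds (about 900 compounds in
total) for exact ground-truth recovery, sets of up to 30 compounds for
the quadratic brute-force oracle comparison, and a 40-compound
reference class for the end-to-end network statistics. A full pipeline
run scales linearly in compounds for fragmentation and in core-group
sizes for pair enumeration; the 192-compound fixture completes in a few
seconds.

## Limitations

- Only single-cut MMPs are considered; multi-site analog relationships
  (double/triple cuts) are out of scope, as are similarity-based AC
  definitions.
- MMP-cliff counts depend on curation details (unit filtering, salt
  stripping, structure canonicalization), so reproducing published
  counts for a public database extract can vary at the margin with
  toolkit and extract version.
- The reduced network links series only through single core-MMPs;
  chains of core transformations appear as paths, not as merged nodes.
- Network rendering is delegated to external tools; the `autoplot()`
  methods are quick diagnostic views, and the GraphML/SIF exports are
  the intended route to publication-quality figures.
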