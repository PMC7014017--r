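---
title: "Methods: the P450/BGC census pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the P450/BGC census pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cypcensus)
```

# The problem

Cytochrome P450 monooxygenases are heme-thiolate enzymes whose family
and subfamily membership is defined operationally, by amino-acid
identity to a named homolog, rather than by function. A comparative
census of a bacterial lineage therefore reduces to a pipeline of small,
well-defined steps: decide which predicted proteins are really P450s,
measure identity to named references, apply the nomenclature thresholds,
aggregate counts per species and family, and cross those counts with the
lineage's secondary-metabolite biosynthetic gene clusters (BGCs). This
vignette records how each step is defined here, which parameters matter,
and what the synthetic validation does and does not demonstrate.

# Triage

Genome-wide candidate lists always contain truncated genes and
spuriously matched proteins. The triage stage separates them with two
sequence-intrinsic rules:

- **Heme motif.** A P450 must match `F..G...C.G` — the heme-binding
  loop whose invariant cysteine ligates the iron. No match means
  `false_positive`.
- **Length.** Motif-bearing candidates shorter than `min_full_length`
  (default 300 aa; bacterial P450s run around 400 aa) are `fragment`.

An optional `E..R` (K-helix salt bridge) check can be enabled via
`triage_params(require_exxr = TRUE)`; it is off by default because the
heme motif alone separates the planted categories cleanly and the
E-x-x-R motif is degenerate in some bacterial families. These rules are
this package's own convention: domain-database searches used in census
studies are an external service, and published counts of fragments and
false positives do not come with reproducible criteria. The rules are
parameters, not constants, so users can tighten or loosen them.

# Percent identity

All classification rests on one number per sequence pair. We use global
(Needleman–Wunsch) alignment under BLOSUM62 with affine gaps (open 10,
extend 1; a gap of length L costs `10 + L`). Identity is

```
100 × identical columns / aligned columns after trimming terminal-gap columns
```

with internal gap columns kept in the denominator. Trimming terminal
gaps approximates what a local aligner would report for near-full-length
homologs while keeping the alignment deterministic and parameter-free;
the alternative denominator (length of the shorter sequence) is
available via `scoring_scheme(identity_denominator =
"shorter_sequence")` and covered by tests. Published censuses used a
BLAST server whose exact parameters and identity definition are not
stated; pairs whose identity falls near a threshold are
definition-sensitive, which is documented here rather than resolved.
The alignment engine is `Biostrings::pairwiseAlignment`; the test suite
checks its scores against an exhaustive enumeration of all alignment
paths on short sequences, so the package's contract does not rest on
trusting the dependency.

# Classification thresholds

The International P450 Nomenclature Committee convention is applied to
the single best hit (ties broken by ascending reference label):

| measured identity | status | assigned labels |
|---|---|---|
| > 55% | `known_subfamily` | best hit's family and subfamily |
| > 40% and ≤ 55% | `new_subfamily_in_family` | best hit's family, provisional subfamily |
| ≤ 40% | `new_family` | provisional family |

The published wording uses strict "greater than" comparisons, so values
exactly at 40 or 55 fall to the lower category; `cyp_thresholds(inclusive
= TRUE)` flips the boundary behaviour for sensitivity analyses.
Provisional labels use a reserved `_NF` / `_NS` infix (`CYP_NF1`,
`CYP110_NS2`) that cannot parse as an official label, and candidates are
processed in sorted `protein_id` order so provisional ordinals are
identical run to run. Official numbers are committee-assigned and out of
scope.

# Census and diversity statistics

The census is a species × family integer matrix (plus a subfamily
sheet); "blooming" is reported as a descriptive top-k ranking, with no
statistical test attached. Two normalized percentages allow comparison
across lineages sampled at different depths:

- P450 diversity % = `100 × F / (P × S)`
- gene-cluster diversity % = `100 × T / (C × S)`

with `F` families, `P` P450s, `T` BGC types, `C` clusters, `S` species.
Both are reported half-up rounded to two decimals; per-species averages
and the share of P450s inside BGCs are half-up rounded to integers.
Base R's `round()` is banker's rounding and does not reproduce printed
comparative tables, hence the dedicated `round_half_up()`.

One convention deserves emphasis: `S` is the **total number of species
analyzed**, including species for which cluster detection returned
nothing — for the packaged cyanobacterial counts that is 114, not the
103 species with detected clusters. This is the only reading under
which the packaged table's printed derived cells are reproduced from its
count rows, and both options remain available to callers since the
functions take `S` explicitly.

# Presence/absence profiles

Family profiles are encoded 3 (present) / −3 (absent), mirroring the
signed convention used by heat-map viewers, and both axes are clustered
agglomeratively under a Euclidean metric. The clustering is written in
the package rather than delegated to `stats::hclust` because
reproducibility here requires a pinned tie-break — among equally close
cluster pairs, merge the one with the lexicographically smallest
combined label set — which `hclust` does not guarantee. Linkage is
average (UPGMA) by default; the original analysis tooling's linkage is
not recorded, so single and complete linkage are offered and tests
assert determinism rather than a specific topology. On tie-free data the
implementation reproduces `hclust` merge heights exactly, and on small
matrices its merge sequence equals a from-scratch brute-force oracle.

# Distance tree and family grouping

As a classification sanity check, a neighbor-joining tree is built on
`d = 1 − identity/100` distances (via `ape::nj`, rows pre-sorted by
label for order independence) and scored by the fraction of multi-member
families that are monophyletic — a family counts as grouped when some
edge bipartition of the unrooted tree separates exactly its members.
Singleton families are excluded from the denominator. This deliberately
replaces a multi-algorithm likelihood/parsimony ensemble on a curated
alignment: the surrogate's role is the grouping check, not publication
of a phylogeny. On additive matrices NJ recovers the generating topology
and branch lengths to numerical precision, which the acceptance tests
exercise on hand-built 4- and 5-taxon trees.

# BGC cross-referencing

Coordinates are 1-based inclusive throughout (GenBank/GFF3 convention;
`from_zero_based()` converts BED-style input). A P450 belongs to a
cluster when its gene interval overlaps the cluster interval by at least
one base on the same species and contig, strand ignored — cluster
boundaries from detection software are approximate and published
membership came from manual mining, so the permissive rule is the
default and a strict containment rule is available. Cluster types are
tallied by their verbatim component-ordered string, so a hybrid
`"NRPS, T1PKS"` is its own type distinct from `"NRPS"`; this convention
is declared, not asserted to be the one used by any particular study.
Interval intersection goes through `GenomicRanges::findOverlaps` and is
checked against a quadratic all-pairs oracle in the tests.

# Synthetic data: what it emulates

The generators produce the study conditions every test runs under:

- **References:** family founders are independent random 400-aa
  sequences rejection-sampled to < 30% mutual identity (random unrelated
  proteins sit far below that, so rejection is rare); subfamily
  exemplars are founder copies mutated to 60–90% identity. Family
  numbers start at 501 to stay clear of real cyanobacterial families.
- **Planted P450s:** reference copies mutated to a target identity by
  uniform substitutions (no indels by default, keeping measured identity
  controllable), with the heme and E-x-x-R motif windows protected so
  triage holds by construction. The mutation loop measures identity
  through the package's own aligner and iterates until within ±2 points
  of target — the contract is checked, never assumed.
- **Decoys and fragments:** random motif-free 350-aa proteins, and
  ~150-aa motif-bearing windows, giving known triage categories.
- **Genomes:** genes laid head-to-tail with 200-base spacers on one
  contig per species; cluster intervals extend 50 bases beyond their
  outermost member genes, so interval intersection recovers exactly the
  planted membership.

The default study (`default_truth_bundle()`) is 4 families × 2
subfamilies, 3 species × (10 planted P450s at 62–90% identity + 2
decoys + 1 fragment), and 6 clusters holding 9 planted P450s. Planted
identities sit at least 5 points clear of both thresholds, because
mutation noise (±2) must not straddle a decision boundary; recovery of
planted labels at this separation is verified in the test suite, and
larger recovery runs (100 queries spanning the high, between-threshold
and new-family bands) run in the acceptance tests. These sizes keep the
full suite fast while exercising every code path; they are stated here
as the package's validation conditions.

What the synthetic data does **not** emulate: real domain architecture,
indel-rich divergence, codon-level structure, detection behaviour of
cluster-finding software, or the reference-database incompleteness of
real censuses. Passing the recovery tests shows the pipeline applies its
stated rules exactly; it does not show that those rules reproduce any
particular published census from raw genomes, which additionally depends
on the external candidate search, cluster detector and database
versions. The packaged published count tables are treated as inputs for
the derived statistics, never as targets the synthetic pipeline could
regenerate.

# Numerical and degenerate-input conventions

- Half-up rounding everywhere a table cell is printed (see above).
- Strict threshold comparisons; boundary identities demote.
- Alignment of an all-gap-trimmed (empty) overlap raises an
  undefined-identity error rather than returning 0 or 100.
- Zero P450s or zero species make diversity percentages a domain error,
  not 0, because the statistic is undefined.
- Single-row matrices degrade to an identity ordering with a warning in
  profile clustering; distance matrices require ≥ 3 sequences.
- All generator and pipeline randomness flows from one explicit integer
  seed; two runs with the same seed write byte-identical artifacts,
  which the acceptance tests compare file by file.

# Known limitations

- Best-hit-only classification ignores conflicting second hits; a
  phylogeny-aware or HMM-based assignment is out of scope.
- Identity near the 40/55 boundaries is sensitive to the identity
  definition (see above); the package exposes the definition rather than
  claiming the one used by any published census.
- Provisional subfamily ordinals depend on the processing order of the
  run that minted them; they are reproducible, not globally meaningful.
- The heat-map stage exports matrices and dendrograms; rendering is left
  to dedicated viewers.
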