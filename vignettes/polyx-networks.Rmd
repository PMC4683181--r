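---
title: "Connectivity and domain composition of homopolymer-repeat protein groups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectivity and domain composition of homopolymer-repeat protein groups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyXnet)
```

## The question and the method

Many eukaryotic proteins contain homopolymeric amino-acid repeats (AARs):
uninterrupted runs of a single residue, such as polyglutamine or
polyalanine tracts.  Beyond their role in expansion diseases, several AARs
can mediate or modulate protein-protein interactions.  `polyXnet`
quantifies, proteome-wide, whether proteins sharing a given repeat type
interact with each other more (or less) often than random expectation, and
which conventional interaction domains co-occur — and positionally overlap —
with each repeat type.

The analysis proceeds in four stages.

**1. Repeat scan.**  Every protein sequence is scanned for maximal runs of
a single standard residue with length at least `minRunLength` (default 4
residues).  Group polyX (X one of the 20 residues) is the set of proteins
with at least one qualifying run of X; a protein can belong to several
groups.  Runs are *pure*: any different letter, including non-standard
codes such as `X` or `U`, terminates a run, and runs of non-standard
letters are never reported.  Coordinates are 1-based and inclusive.

**2. Network extraction.**  From a binary interactome (an undirected simple
graph; duplicate, reversed and self-edges are collapsed or dropped at
read time), each group's network keeps exactly the edges incident to a
member, classified as *type a* (both endpoints members) or *type b* (one
endpoint a member).  Edges between two non-members are discarded, so both
indexes below are invariant to anything happening outside the group.

**3. Connectivity indexes and controls.**  Two indexes summarize within-group
connectivity:

* the **proportion index** \(|a| / (|a| + |b|)\), and
* the **per-node index** \(2|a| / n\), the mean within-group degree, where
  \(n\) by default counts the members with at least one interaction of any
  type (`present_members`).

Because both indexes depend strongly on group size and on the interactome's
density, each is normalized against `nControls = 5` random control groups of
identical size drawn from the proteome: the reported statistic is the mean
of the five ratios raw/control, with its SEM (sample SD / \(\sqrt{5}\)).
A Yates-corrected chi-squared test compares the group's (a, b) split with
the control counts; one-way ANOVA and Dunnett many-to-one comparisons
(against the group whose mean ratio is closest to 1) test differences
across groups; the Pearson correlation between the two mean indexes across
groups checks their concordance.

**4. Domain composition.**  For each group, every domain annotated on a
member is tested for overrepresentation against the proteome background
with the one-sided hypergeometric tail, Benjamini–Hochberg adjusted within
the group's family of domains (threshold `alpha = 0.05`).  For significant
repeat–domain pairs, the positional overlap stage counts the proteins in
which some repeat run and some domain instance share at least
`minOverlap = 4` residues, and reports the fraction with the band labels
`none`, `partial` (< 25%) and `25-100%`.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `minRunLength` | 4 residues | repeat-length threshold defining polyX membership |
| `nControls` | 5 | random control groups per polyX group |
| `alpha` | 0.05 | significance level (chi-squared flag, BH threshold) |
| `minOverlap` | 4 residues | repeat/domain positional-overlap threshold |
| `minGroupSize` | 2 | groups below this size are skipped (singleton groups carry no type-a information) |
| `chi2Controls` | `"mean"` | comparison column of the 2×2 table: rounded mean, or summed ("pooled") control counts |
| `perNodeDenominator` | `"present_members"` | node set the per-node index divides by |

The per-node denominator is a genuine modelling choice: dividing by all
members penalizes proteins absent from the interactome, while dividing by
type-a nodes only conditions on connectivity.  `present_members` — members
with at least one known interaction — is the default because the group
networks are built from proteins with known interactions in the first
place; both alternatives are selectable.

## What the synthetic generator emulates

`simulateProteome()` draws sequences i.i.d. from a vertebrate-like residue
composition and plants runs of chosen residue, length and carrier count at
recorded positions.  Accidental background runs at or above the threshold
are suppressed by resampling the offending windows, so planted group
membership is *exact* by construction (an off switch exists; ground truth
is then recomputed by scanning).  `simulateInteractome()` is a
planted-partition (stochastic block) model: within-group pairs get an edge
with probability \(p_{in}\), all other pairs with \(p_{out}\); the
expected per-node index ratio of the planted group is then approximately
\(\rho = p_{in}/p_{out}\).  `simulateDomainAnnotations()` plants a domain
carried by group members with probability \(q_{in}\) (others \(q_{out}\)),
positioned to overlap the planted run by at least 4 residues with
probability \(w\) and strictly away from it otherwise, plus uniform decoy
domains.

Real interactomes are not planted-partition graphs: they have heavy-tailed
degree distributions, ascertainment bias toward well-studied proteins, and
correlated annotation structure.  Passing calibration and recovery tests on
these fixtures therefore demonstrates that the *computations* are correct
and the normalization is unbiased under exchangeability — not that any
particular biological dataset will show a given effect size.

## Numerical and design choices

* **Normalization bias.**  The normalized index is a ratio of (functions
  of) counts, so \(E[\text{raw}/\text{control}] \approx \rho\,(1 +
  \mathrm{CV}^2(\text{control}))\) by second-order Taylor expansion.  With
  the simulation sizes used here (about 18–40 expected within-group control
  edges) the bias is 2–6%, visible in the calibration results; it shrinks
  as counts grow and affects polyX and control groups identically.
  Null-calibration runs use an edge probability of 0.05 over a universe of
  500 proteins and groups of 40, giving index noise comparable to mid-sized
  repeat groups in a real interactome.
* **Chi-squared control column.**  Comparing the group's (a, b) counts to
  the *rounded mean* of the five control columns follows the natural
  reading of "the average of the control random networks", and is the
  default.  Statistically it treats a mean (whose variance is one fifth of
  a single replicate's) as one observed sample, so the test is
  conservative: in null calibration it rejects at well below the nominal
  0.05.  The `pooled` alternative sums the five control columns, which is
  the conventional, correctly calibrated 2×2 construction — the package's
  calibration utilities report both rates.
* **Degenerate controls.**  A control replicate with no interactions, or
  with zero type-a edges, leaves a ratio undefined; such replicates are
  redrawn with a fresh deterministic sub-seed (up to 100 attempts, each
  logged) rather than dropped, so \(n = 5\) is preserved without biasing
  toward connected controls more than the definition requires.
* **Seeding.**  All randomness flows from one master seed; every
  (group, replicate) pair derives its own sub-seed by integer hashing, so
  results are byte-reproducible and adding a group does not shift any
  other group's controls.
* **Dunnett reference.**  Adjusted p-values use the equicorrelated
  multivariate-t distribution via `multcomp`; its quasi-Monte-Carlo tail
  evaluation runs under a fixed internal RNG substream so repeated runs
  produce identical output files.
* **Undefined indexes.**  Groups whose own network has no interactions are
  excluded from the battery and listed with reasons in `summary_stats.tsv`
  (and the `skipped` element), not silently dropped.
* **EASE mode.**  The enrichment default is the standard hypergeometric
  tail; the conservative EASE variant (decrementing the observed overlap by
  one) is available as `mode = "ease"` for compatibility with DAVID-style
  scores.

## Simulation-study sizes

The packaged calibration utilities (also used by the test suite and
`scripts/acceptance.R`) use: 1000 null datasets (universe 500, group 40,
edge probability 0.05); 200 planted-partition replicates per effect size
(universe 600, group 60, \(p_{out} = 0.01\), \(\rho \in \{2.4, 0.4\}\),
polyQ-like enrichment and polyL-like depletion respectively); 100
enrichment replicates (background 400, group 40, \(q_{in} = 0.5\),
\(q_{out} = 0.05\), 50 decoys at rate 0.05); and overlap recovery with
planted \(w \in \{0, 0.5, 1\}\) over 150 co-occurring proteins.  These
sizes put the Monte-Carlo standard error of every checked quantity well
inside its acceptance band while keeping a full run in the low minutes on
one CPU.

## A worked example

```{r example, eval = FALSE}
st <- simulateStudy("study", seed = 1)
res <- runFullAnalysis(st$paths$proteome, st$paths$interactome,
                       st$paths$domains, outDir = "analysis", seed = 1)
subset(res$connectivity$results, residue == "Q",
       c(type_a, type_b, mean_norm_proportion, mean_norm_per_node, chi2_p))
```

With the default simulated study (one planted polyQ group of 40 in 400
proteins, \(p_{in}/p_{out} = 2.4\)) the polyQ row shows normalized ratios
well above 1 and a significant chi-squared test, while unplanted groups are
absent (no repeats survive suppression) or hover near 1.

## Known limitations

* Inputs must share one id namespace; no accession mapping is performed
  (the pipeline warns when interactome ids rarely match the proteome).
* Only pure, uninterrupted runs define groups; repeats fragmented by even
  a single different residue are not merged.
* Interaction multiplicity and evidence codes are ignored: an edge exists
  or it does not.
* The enrichment background and raw statistic of historical DAVID runs are
  not exactly recoverable, so results on real data are expected to differ
  in detail from any analysis performed with that service.
* The overlap rule requires a single (run, domain-instance) pair to share
  `minOverlap` residues; overlap is not summed across runs.
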