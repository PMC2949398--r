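---
title: "ccanet: models, null hypotheses and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ccanet: models, null hypotheses and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccanet)
```

## The inference problem

Large tumour sequencing screens record, per sample and gene, whether the
gene was sequenced and whether it carried a somatic mutation. Two genes
whose mutations co-occur across samples more often than their marginal
frequencies predict are candidates for cooperative tumorigenesis; two
genes whose mutations avoid each other are candidates for functional
redundancy within one pathway. `ccanet` infers these pairwise relations,
assembles them into an undirected network, and provides the topological
and biological follow-up analyses that make the network interpretable.

A crucial feature of real screens is *partial sequencing*: different
studies screen different gene panels, so a sample not sequenced for a
gene is not a wildtype observation. All pairwise statistics condition on
the co-sequenced sample set; the `NA` status code is load-bearing
throughout, and absent cells in long-format input default to
not-sequenced unless the user asserts `assume_sequenced`.

## Pair test

For each unordered pair we form the 2×2 table (AandB, AnotB, BnotA,
notAnotB) over co-sequenced samples and compute a two-sided Fisher exact
p by point-probability summation: all hypergeometric tables with the
observed margins whose probability does not exceed the observed table's
(with a 1e-7 relative tolerance on the log scale) contribute. This is the
convention of mainstream implementations and is verified in the test
suite both against full-margin enumeration from factorials (to 1e-9 for
N ≤ 30) and against `stats::fisher.test`.

Direction comes from the sample odds ratio; because anti pairs typically
have AandB = 0, a 0.5 continuity correction is applied to *all* cells
whenever any cell is zero, keeping the estimate finite and directional.
An OR of exactly 1 is directionless and never linked. One two-sided test
serves both relations — co and anti are the two tails of the same
alternative, distinguished afterwards by the OR.

Linking uses the raw p ≤ 0.02 (cutoff configurable). Benjamini–Hochberg
q-values over all performed tests are attached for reporting but do not
gate edges: the reference analysis this package reimplements gated on raw
p and quoted the corresponding FDR level descriptively. Pairs with fewer
than `min_cosequenced` overlapping samples are skipped (default 1, i.e.
nothing is skipped unless requested — sparse panels make tiny overlaps
uninformative, but the default stays permissive).

## Network metrics

Degree counts all incident edges; the clustering coefficient is
C = 2·e(N(v))/(k(k−1)) with C := 0 for k < 2. Whether k < 2 nodes enter
the network-average C changes the statistic, so
`mean_clustering_coefficient(..., drop_low_degree = TRUE)` exposes the
exclusion convention; the default counts them as 0. Anti edges count in
degree and C by default (they are a sub-percent minority in realistic
networks and the reference analysis does not state an exclusion);
`node_degrees(..., relation =)` filters when needed. Distances are BFS —
identical to Dijkstra on unit weights, which the tests assert against
igraph — and unreachable pairs are `Inf`, excluded from correlations.
Components and the optional greedy-modularity module detection are
delegated to igraph; detection is a convenience flagged experimental,
because module-level statistics are defined over *supplied* labels.

## Randomization engine

Every empirical test uses p = (T+1)/(R+1), where T counts null
replicates ≥ (tail `ge`) or ≤ (tail `le`) the observed statistic. The +1
in numerator and denominator makes the p-value achievable-minimum
1/(R+1), never 0, and super-uniform under the null — both properties are
asserted in the suite at 10-bin resolution.

Null models, chosen per statistic:

* **Pathway co-membership**: uniform edge rewiring — same node set, same
  link count, degree *not* preserved, edges drawn uniformly without
  replacement from all unordered pairs. This is the weakest (most
  conservative about topology) reading of "randomly re-connected with the
  same number of links"; a degree-preserving double-edge-swap variant is
  available behind `degree_preserving = TRUE` for sensitivity analysis.
* **Signal-type usage**: the statistic lives on links, not on gene pairs,
  so the null resamples the same number of links uniformly from the
  signaling network's typed links and recounts activation/repression.
  The joint (activation, repression) null grid is returned for heat-map
  inspection. Unknown-type links are excluded from every denominator —
  the only convention under which the whole-network expected fractions
  reproduce the published 47.5/14.6/37.9% composition.
* **AD comparison**: random groups are unordered node pairs drawn
  uniformly from the *network's* nodes (not all genes): the question is
  whether linked pairs differ from unlinked pairs of the same universe.
  The compared statistic is the group median of AD = |freq_A − freq_B|,
  on raw (not length-corrected) frequencies by default; pass corrected
  values to switch.
* **Sample–module distribution**: per sample, the number of mutated
  module genes is held fixed and those mutations are reassigned uniformly
  over module genes. This is the simplest null consistent with a joint
  (M, N) grid over the two modules. Its power depends on per-sample
  counts: a sample with many module mutations hits the larger module
  almost surely under the null, so the all-samples-hit-module-one
  statistic is only discriminating for sparse screens — which
  whole-genome discovery cohorts are.

## Frequency definition

Mutation frequency is mutated/sequenced per gene (a gene mutated in 9 of
10 sequenced samples has frequency 0.9), optionally divided by gene
length in bp to remove the target-size confounder. The inverted reading
(sequenced/mutated) is incompatible with frequencies quoted as
percentages below 1 and is not offered.

## Synthetic-data generator

The generator states a simple world with exact ground truth:

* each gene mutates independently per sample at its baseline frequency
  (default log-uniform on [0.01, 0.3], emulating the heterogeneity of
  real per-gene frequencies);
* a planted co pair shares a latent driver: with probability q the event
  fires and both genes are set mutated — co-occurrence above chance plus
  near-equal marginal boosts, so co pairs also have similar frequencies;
* a planted anti pair has an exclusive driver: with probability e exactly
  one of the two (fair coin) is set mutated and both baselines are
  suppressed in that sample, so planted exclusivity is exact rather than
  merely discouraged;
* sequencing coverage is an i.i.d. per-cell mask with probability c.
  Real panels are structured per study, but an i.i.d. mask exercises the
  co-sequenced-restriction logic equally well.

Expression profiles decay along the network: the root of each component
draws a latent profile (sd 3 — tissue-atlas signal sits well above
per-gene noise, and a ~3:1 signal-to-noise ratio keeps distance structure
visible without making it trivial), and a gene at distance d receives
decay_alpha^d × latent + N(0, noise_sd²). The *expected* group-mean
similarity curve is strictly decreasing in distance for any latent scale
(verified by closed form and Monte-Carlo in the tests); a *single seed's*
curve at 79 tissues need not be, because distant distance groups contain
few pairs and a lone |r| estimate has sd ≈ 0.1. Tests therefore assert
the negative grouped correlation per seed (majority over seeds) and
strict decrease of the Monte-Carlo-averaged curve, which is the form of
the property the generator actually guarantees.

What a green test does *not* establish: robustness to structured
screening panels, per-sample mutation-load heterogeneity, subtype
mixtures, copy-number events, or mutation-calling error — none of which
the generator emulates (deliberately; see Non-goals in the interface
documentation).

## Numerical choices

* Fisher p: log-scale point probabilities with a 1e-7 relative tolerance
  when comparing table probabilities; p clamped to ≤ 1.
* Rank-sum test: exact enumeration of all C(n, n_a) assignments with
  mid-ranks for combined n ≤ 12 (a 1e-9 slack absorbs float ties);
  normal approximation with tie correction and 0.5 continuity correction
  above; fully tied data give p = 1.
* Spearman rho: Pearson on mid-ranks; p from the t approximation —
  matching the tie-handling of standard software, and verified against a
  rank-then-Pearson oracle to 1e-12.
* Hypergeometric enrichment: `phyper` upper tail at x − 1, equal to the
  enumeration oracle to 1e-9 on small universes.
* Pajek files: 1-based contiguous vertex ids, quoted labels, edge value
  1 = co / 2 = anti; a NET file without edge values reads as all-co,
  since published network files do not always encode the relation.
* Master seed fans out to per-stage substreams via a fixed affine map
  mod 2^31 − 1, so stages are individually reproducible and reordering
  one stage cannot silently shift another's stream.

## Known limitations

* The pair test is marginal: it does not adjust for per-sample mutation
  load, so hypermutated samples can induce spurious co-occurrence. Modern
  exclusivity methods (e.g. DISCOVER-style per-sample rates) address
  this; here the marginal Fisher test *is* the modelled method.
* The module workflow requires exactly two modules with supplied labels;
  the greedy detector is not a substitute for curated modules.
* The enrichment routine is a generic hypergeometric over-representation
  test over user-supplied GMT sets; it does not replicate any specific
  annotation tool's score variant.
* Randomization p-values inherit Monte-Carlo granularity 1/(R+1);
  quantities quoted near that floor (e.g. "< 2×10⁻⁴" at R = 5000) are
  bounds, not point estimates.
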