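---
title: "Models and methods behind seldiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind seldiv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seldiv)
```

`seldiv` implements the molecular-evolution toolchain used to dissect the
evolution of small plant gene subfamilies such as the NIP III (NIP2)
aquaporins: codon-alignment construction, paralog dating by fourfold
transversions, distance trees, codon site/branch models of selection,
functional-divergence coefficients between clades, and a
specificity-determining-position scan.  This vignette explains each model,
its assumptions and tunable parameters, the numerical choices taken, and
what the synthetic-data module does and does not emulate.

## Codon alignments

All codon-level analyses run on a `codon_alignment`: aligned CDS rows,
column-synchronized with a protein alignment, gaps occupying whole codons.
`backtranslate()` builds it from an externally computed protein alignment
plus unaligned CDS; the protein aligner itself (MAFFT or similar) is
deliberately out of scope.  Back-translation verifies that every codon
translates to its aligned residue, strips a genuine terminal stop codon
(one codon beyond the aligned residues) silently, and rejects internal
stops.

`filter_codon_columns()` reproduces the usual manual cleanup of family
alignments: a codon column is dropped when fewer than `min_present` rows
(default 3) carry data, i.e. columns where all sequences except one or two
are gaps.  Columns with intermediate gap fractions are kept: only the
removal clause is applied, which is the conservative reading of that rule;
the threshold is exposed for stricter choices.  All coordinates in reports
are 1-based column indices of the filtered alignment — the R ecosystem's
convention — and `kept_map` translates them back to pre-filter columns.
Per-sequence residue numberings (as in `sdp_table()`) are additionally
provided because published site labels are often given in the coordinates
of a reference sequence rather than the alignment.

## 4DTv distances

`d4dtv()` measures the divergence of a duplicate pair as the proportion of
transversions at third positions of conserved fourfold-degenerate codons.
A site qualifies only when both codons come from a fourfold box (GCN, CGN,
GGN, CTN, CCN, TCN, ACN, GTN) *and* encode the same amino acid; serine
AGY, leucine TTR and arginine AGR codons never qualify because their third
position is not fully degenerate.  The statistic is the uncorrected
proportion: it starts at 0 for identical copies and saturates near 0.5,
because at equilibrium two of the four third-position nucleotides are
transversional with respect to any given one.  No substitution-model
correction is applied; the raw proportion is what the 0-to-0.5 range
describes, and corrected variants are out of scope.  Sites containing
ambiguity codes are excluded; a pair with no qualifying sites returns an
explicit `NA`, never 0.

## Distance trees and the strict clock

`p_distance()` offers plain p-distances for protein or nucleotide data and
a transversion-only mode in which only purine–pyrimidine differences enter
the numerator while the denominator remains all compared positions.
Pairwise deletion (the default) drops positions gapped in either member of
a pair.  Both protein and transversion modes are provided because distance
trees for this kind of family have been published under both conventions;
neither is asserted to be the canonical one.

`neighbor_joining()` delegates to the Saitou–Nei implementation in `ape`
and clamps negative estimated branch lengths to zero (reported via a
message), matching the common display convention.  On additive distances
the NJ topology and branch lengths are exact, which the test suite checks
against a hand-built four-taxon tree.  `bootstrap_support()` resamples
alignment columns — codon columns when the input is a codon alignment, so
codon structure is never broken — and reports, for each internal edge of
the point-estimate tree, the percentage of replicates containing that
bipartition.  Replicates are driven entirely by column indices drawn under
the given seed, so supports are invariant to the row order of the input.

`strict_clock_age()` is the one-parameter global-clock estimate: given a
calibration split of age `t_cal` spanning distance `d_cal`, a pair at
distance `d` is dated at `t_cal * d / d_cal`.  It is a deliberate
simplification of likelihood-based clock dating — adequate for the
order-of-magnitude duplication dating it is used for, and nothing more.

## Codon site models

The substitution process is the GY94-style codon model on the 61 sense
codons of the standard code: the rate from codon *i* to *j* is zero unless
they differ at one position, and otherwise proportional to the target
frequency `pi_j`, multiplied by `kappa` for transitions and by `omega` for
nonsynonymous changes.  The generator is scaled to one expected
substitution per codon at stationarity, so branch lengths are in
substitutions per codon.  Codon frequencies default to F3x4 (products of
position-specific nucleotide frequencies estimated from the alignment,
with a half-count of smoothing and a small floor so no sense codon has
zero frequency); F1x4 and equal frequencies are available, and equal
frequencies are convenient in tests because they make closed-form
expectations easy.

Likelihoods are computed by Felsenstein pruning over a compiled kernel,
with site-pattern compression and per-pattern rescaling.  Gap codons are
missing data (partial-likelihood vectors of ones).  Transition matrices
come from the symmetric eigendecomposition available for reversible
generators; the test suite cross-checks them against a dense matrix
exponential and checks the pruning likelihood against brute-force
enumeration of internal states on four-taxon trees.

Four site models are fitted by maximum likelihood over branch lengths,
`kappa` and the omega distribution:

* **M0** — one `omega` for all sites;
* **M3** — `K` discrete classes (default `K = 3`, configurable; published
  analyses do not always state `K`, and a fitted class can collapse onto
  another when the data support fewer components);
* **M7** — `omega ~ Beta(p, q)` on (0, 1), discretized into 10
  equal-probability classes at the bin medians (inverse CDF at
  `(2k + 1)/20`), a deterministic quadrature;
* **M8** — with probability `p0` the M7 beta, else a class at
  `omega_s >= 1`.

M0-vs-M3 (4 df) tests rate heterogeneity among sites; M7-vs-M8 (2 df) is
the stringent positive-selection test, since M8 differs from its null only
by the `omega > 1` class.  No boundary-mixture correction is applied to
the chi-squared reference, matching common practice; this makes the test
conservative, and the suite verifies the null rejection rate stays at or
below nominal on data simulated under M7.

Optimization is bounded quasi-Newton (L-BFGS-B) on log/logit-transformed
parameters, with branch lengths in `[1e-7, 30]`, `kappa` in `[0.05, 50]`,
beta shapes in `[0.005, 50]` and `omega_s` in `[1, 30]`.  Fits accept an
`init_fit` warm start from the nested model; the M8 fit then runs two
deterministic starts — a replica of the M7 solution (`p0 -> 1`), which
guarantees the nested log-likelihood ordering, and a start with the
selection class switched on (`p0 = 0.9`, `omega_s = 3`), because the
replica sits on a flat boundary of the likelihood.  Additional random
restarts (seeded) are available via `n_starts`.  Convergence is governed
by the optimizer's `factr` (default `1e8`, about 1e-8 relative).

Positively selected sites are reported by naive empirical Bayes (NEB):
the posterior that a site belongs to an `omega > 1` class, from the fitted
mixture.  Sites at or above `report_floor` (default 0.7) are listed and
those at or above `high` (default 0.95) starred, following the usual
report-table convention of listing candidates but trusting only the
starred ones.  NEB plugs in point estimates and is known to be optimistic
when the selection-class parameters are poorly determined; the test suite
therefore checks its precision on simulated data, and
`beb_lite_posteriors()` offers an exploratory Bayes-empirical-Bayes-style
variant that averages the posterior over a likelihood-weighted grid of
`(p0, omega_s)` values.  Full BEB integration over all parameters is not
implemented; NEB is the primary contract.

Branch models share one `omega` across sites: `one_ratio` (a single shared
`omega`; identical to M0) versus `free_ratio` (one `omega` per branch,
`2E + 1` free parameters for `E` edges), compared by an LRT with
`E - 1` df.  Branches with `omega > 1` are flagged — the textual
equivalent of the red-branch figure convention, available as an annotated
Newick via `write_flagged_newick()`.  Branches whose fitted length hits
the zero bound are reported as unidentifiable rather than flagged, since
`omega` carries no information on a zero-length branch.

## Functional divergence between clades

Type-I functional divergence (rate shift after duplication or speciation)
is estimated from per-site substitution counts inferred by Fitch parsimony
within each cluster's subtree (`change_count_table()`).  Gaps are missing
data and never force a change.  The site likelihood is a two-state
mixture: with probability `theta_I` the site's rate is drawn independently
in the two clusters (product of two gamma–Poisson marginals, i.e. negative
binomials with shared shape `alpha` and cluster means `D1`, `D2` fixed at
the observed averages), otherwise one shared gamma rate generates both
counts (a closed-form bivariate gamma–Poisson).  `theta_I` is constrained
to `[0, 1]` (boundary hits are flagged), `alpha` to `[0.05, 100]` for
stability.  The standard error comes from the observed Fisher information,
the LRT compares against `theta_I = 0` with `alpha` re-optimized under the
null, and the per-site posterior `Q_k` of the rate-shift state yields the
critical amino acid sites (`type1_caas()`, default `Q_k > 0.9`).

Type-II divergence (radical property shift at otherwise conserved sites)
uses a deliberately simple closed-form estimator rather than a numeric
clone of any existing program.  Applicable sites are monomorphic within
both clusters; among applicable sites whose cluster-ancestral states
differ, a difference is radical when the two residues fall in different
property groups (default partition: charge — `{K,R,H}`, `{D,E}`, rest;
polarity and hydrophobicity partitions are shipped as alternatives).  The
background radical probability `p_r0` is the radical fraction among
within-cluster substitution events enumerated by a full Fitch pass over
the remaining sites (0.5 if none exist), and
`theta_II = (pi_R - p_r0) / (1 - p_r0)`, which is negative when radical
differences are rarer than the background predicts — a legitimate outcome,
reported as such.  The standard error is a binomial delta-method
approximation treating `p_r0` as fixed.  Fitch ancestral ties are broken
by the cluster's column consensus, then alphabetically — an arbitrary but
deterministic rule, applied identically everywhere.

## Specificity-determining positions

`column_mi()` scores a column by the mutual information (bits) between
residue identity and group label, with group-conditional residue
distributions smoothed by `lambda` pseudo-counts spread according to the
overall residue frequencies (default `lambda = 1`; `lambda = 0` is the
plug-in estimate, bounded by `log2` of the number of groups).  Columns
with more than 10% gaps are not scored.  Significance comes from
`n_shuffles` permutations of the group labels across sequences — the same
permutation applied to every column within a replicate, drawn over the
sorted id list so results do not depend on input order — giving
`Z = (MI - mean_shuffle) / sd_shuffle` (zero when the shuffle variance is
zero).

The number of reported SDPs is chosen by the Bernoulli estimator: for each
candidate count `L`, with `eps_L` the standard-normal upper-tail
probability of the `L`-th ranked Z-score, `B(L)` is the log10 binomial
tail probability that at least `L` of the `N` scored columns exceed that
score by chance; the cutoff minimizes `B(L)` (ties to the smallest `L`),
and only columns with positive `Z` are ever selected, so an alignment of
identical sequences yields an empty SDP set.  An empirical-tail variant of
`eps_L` (pooling all shuffle Z-scores) can be supplied through the `tail`
argument.  Published SDP servers use their own unreleased smoothing and
significance machinery, so numeric parity with any particular server's
table is explicitly not claimed; the scan is validated instead by
recovering planted SDPs in simulated alignments.

## The synthetic-data module

Every analysis stage has a seeded generator whose output satisfies the
consuming stage's input contracts:

* `simulate_codon_alignment()` draws per-site omega classes from a mixture
  and evolves a root codon (from the stationary distribution) down a tree
  — the simulation counterpart of the site models;
* `simulate_rate_shift_counts()` draws shared or independent
  gamma(`alpha`, `alpha`) rates and Poisson counts — the Type-I model's
  own data-generating process;
* `simulate_grouped_alignment()` plants group-separated columns (with a
  5% default error rate) on an i.i.d. background shared across groups;
* `simulate_paralog_pair()` builds fourfold-degenerate codons whose third
  positions diverge under a K2P process, with a saturation mode drawing
  both copies uniformly — the infinite-time limit used to verify the 0.5
  asymptote of the 4DTv statistic.

These simulators emulate the *statistical* structure the methods assume —
site-independent substitution, no indels, no rate variation along a
sequence beyond the modelled classes, uniform codon composition within a
box — and none of the biological structure of real aquaporins
(transmembrane helices, NPA motifs, domain architecture, alignment
error).  Passing tests therefore demonstrate correctness of the
estimators under their own assumptions, not robustness to real-data
violations of them.

## Problem sizes and determinism

The test and acceptance suites run at desk scale, chosen to balance
statistical resolution against runtime: parameter-recovery checks use 6–8
taxa and 150–500 codons; the NEB precision check uses 16 taxa to give
per-site posteriors enough resolution; the null-calibration check runs 50
replicates of the M7-vs-M8 test; the Type-I checks use 400–500 sites; the
SDP recovery check plants 5 columns among 200.  Reproducing the numbers of
any particular published family analysis requires that family's sequence
set, which this package intentionally does not bundle; headline statistics
of the NIP III analyses (for example `theta_I = 0.145 +/- 0.041` between
monocot and dicot clades, or 4DTv values of 0.087–0.441 for grass and
cucurbit paralog pairs) serve as orientation for the magnitudes these
tools produce on real families.

Every stochastic routine takes an explicit seed, restores the caller's RNG
state, and is a pure function of its parameters and seed; the pipeline
propagates one global seed and writes it into its report metadata.
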