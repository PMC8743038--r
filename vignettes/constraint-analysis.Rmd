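---
title: "Comparative analysis of purifying selection across species and pathways"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative analysis of purifying selection across species and pathways}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dndscape)
```

## The problem

Host-associated microbial communities let us compare evolutionary dynamics
across tens of coexisting species at once.  For each species, the dominant
lineages resident in two different hosts have been diverging for some time;
counting nonsynonymous and synonymous differences between them gives a
per-gene dN/dS whose behaviour as a function of synonymous divergence (dS)
summarizes the direction and strength of selection.  Empirically, dN/dS
declines as dS grows: purifying selection dominates over long timescales.
This package provides the downstream comparative machinery for such data:
it consumes per-gene substitution-count tables (produced by an upstream
variant-calling pipeline, which is out of scope here), pools them into
pathway-level units shared across species, and asks which pathways and
which species deviate from the community-wide trend.

## The model

dN/dS as a function of dS is modelled with two parameters: a fraction
`f_sel` of nonsynonymous sites subject to (effectively one class of)
purifying selection, and a divergence scale `d_star` at which divergence at
the selected sites saturates under mutation–selection balance:

$$
\widehat{dN/dS}(d_S) \;=\; (1 - f_{\mathrm{sel}})
  \;+\; f_{\mathrm{sel}}\,\frac{1 - e^{-d_S/d^*}}{d_S/d^*} .
$$

At `dS -> 0` the expectation is 1 (too little time for selection to leave a
footprint); as `dS -> Inf` it falls monotonically to the asymptote
`1 - f_sel`.  `d_star` is a composite scale standing in for the selection
coefficient: `s` is proportional to `1/d_star` up to the (unmodelled)
mutation rate, so `s` in absolute units is deliberately out of reach.
`model_curve()` evaluates the curve with the `dS -> 0` limit handled
analytically; `fit_model()` minimizes squared residuals of `log(dN/dS)`
(the ratio spans orders of magnitude, and log residuals make a
multiplicative-noise model additive) over a fixed coarse grid
(`f_sel` in steps of 0.01; 50 log-spaced `d_star` knots in `[1e-4, 1e-1]`)
followed by bounded quasi-Newton refinement — global, deterministic, and
cheap.  Points with `dN/dS <= 0` cannot enter a log fit and are dropped
with a warning; data consistent with neutrality (`f_sel ~ 0`) flag
`d_star` as unidentifiable rather than reporting a meaningless scale.

## Pooling and coarse-graining

All group-level ratios are "ratios of sums": the four count fields are
summed over the genes (and lineage pairs) of a group and the ratio is taken
once.  Averaging per-gene ratios would be dominated by genes with tiny
synonymous counts; pooling is robust to them.  A cell of the species x
pathway matrix is masked when its pooled synonymous-difference count falls
below `min_support` (default 10) or when pooled dS is exactly zero (ratio
undefined; such cells are counted and reported, never coerced to 0 or
infinity).  Record filtering drops genes with fewer than `min_s_opp`
(default 10) synonymous opportunity sites and whole lineage pairs whose
genome-wide dS leaves `[min_pair_dS, max_pair_dS]` (defaults 0 and 0.75).
The source study does not state how its points were filtered, so these are
exposed configuration with documented defaults, not a claim of
equivalence.  A Jukes–Cantor multiple-hit correction is available by flag
but off by default: over the dS range of interest (below ~0.1) raw
proportions are adequate.

## Permutation tests

To ask whether a *species* is under exceptional constraint, its statistic
is the mean dN/dS over its unmasked pathway cells, and the null is built by
shuffling values among species independently within every pathway column.
This conditions on each pathway's composition and on the missingness
geometry (masked cells never receive values), so each species is compared
against "a typical species with the same pathway repertoire".  The
*pathway* test is the exact mirror, shuffling within species rows;
`test_pathways(m)` equals `test_species(t(m))` bit for bit, by
construction.  Flags follow the 95% percentile interval of the null
(`stronger` below the 2.5% quantile, `weaker` above the 97.5%).  Two-sided
empirical p-values (absolute deviation from the null median, add-one
corrected, so `p >= 1/(B+1)`) and Benjamini–Hochberg q-values are reported
alongside for reuse, but the headline flags are the percentile CIs.  The
statistic defaults to the mean (the source analysis does not name its
statistic; the median is available by flag), and B defaults to 10,000.
For tiny matrices an `exact = TRUE` mode enumerates every combination of
within-column permutations, which the test suite checks against naive
enumeration oracles.

## Cross-species statistics

*Taylor's law.*  Across pathways, `log10(variance)` of dN/dS over species
is regressed on `log10(mean)`.  Slope 2 is equivalent to a constant
coefficient of variation; `taylor_regression()` reports the OLS slope, its
standard error, `t = (slope - 2)/se` with `n_pathways - 2` degrees of
freedom, and both one- and two-sided p-values.  The source study prints a
t of 0.684 with P = 0.248, which is consistent with a one-sided (upper
tail) convention; both conventions are therefore reported and labelled,
with the two-sided value used by this package's own tests.

*Constraint correlation vs phylogeny.*  For every species pair sharing at
least `min_shared_pathways` (default 5) unmasked pathways, the Pearson
correlation of their `log10` pathway-dN/dS profiles is computed (Spearman
by flag; the correlation metric is unstated in the source).  The OLS slope
`beta` of these correlations on cophenetic distance measures how fast
shared constraint decays along the phylogeny.  Correlations that share a
species are not independent, so significance comes from a Mantel-style
permutation: species labels of the distance matrix are permuted jointly
and the slope recomputed; the analytic OLS p-value is reported only for
transparency.  Units of `beta` are per unit branch length of whatever tree
or distance matrix the user supplies — the source study does not state how
its distances were computed.

## The synthetic world

The generator stands in for the study's human-gut divergence data, whose
inputs are not deposited.  Its defaults state one world and the test suite
does not tune them per run:

* ~40 prevalent species, 20 pathways, 25 genes per pathway, 30 host
  lineage pairs per species; 700 nonsynonymous and 250 synonymous
  opportunity sites per gene (typical bacterial gene length, ~3:1
  opportunity ratio).
* Pair-level neutral divergence `dS_t` lognormal with median 0.01 and
  log-sd 1, truncated to `[1e-4, 0.1]` — a few-decade spread matching
  within- vs between-host comparisons.
* Per gene, `s_diff ~ Binomial(s_opp, dS_t)` and
  `n_diff ~ Binomial(n_opp, dS_t * curve * noise)` with mean-one lognormal
  gene noise (log-sd 0.2).  Binomial (not Poisson) counts keep differences
  bounded by opportunities by construction; success probabilities are
  capped below the multiple-hit singularity at 3/4, and parameter
  combinations pushing more than 1% of genes past it are rejected.
* Constraint `f_sel[species, pathway]`: each pathway's baseline is uniform
  on `[0.5, 0.99]`, and species deviations evolve along a coalescent tree
  (branch lengths normalized to maximum tip distance 1) under a stationary
  Ornstein–Uhlenbeck process (sd 0.1, reversion rate `lambda_OU = 2`), the
  minimal stationary process whose tip covariance decays as
  `exp(-lambda_OU * d)` — realizing "constraint is moderately conserved
  through evolutionary time" with a recoverable decay-rate truth.

Two deliberate design points deserve note.  First, the *constant-CV world*
(`cv_target`): inverting a target cell dN/dS through the saturating curve
is infeasible when typical `dS ~ d_star`, because the pooled cell
expectation is floored at the dS-weighted saturating term (~0.4 at the
defaults); a heavy-tailed CV >= 1 target would collapse under clipping.
The constant-CV world therefore realizes constraint in the saturated
regime — the cell's expected dN/dS equals the drawn target `omega`
directly, independent of the pair's dS, with `f_sel = 1 - omega` recorded
as truth — which enforces the CV exactly and without clipping.  Second,
the *no-signal setting* is `lambda_OU = Inf` (tip deviations i.i.d.), not
a large finite rate: on a coalescent tree normalized to maximum distance
1, the closest species pairs sit at distances of order `1/100`, where even
`lambda_OU = 100` leaves correlation ~0.4 that a Mantel test with ~200
pairs genuinely detects.

What a green test does *not* establish: the generator draws dS
independently per pair (no shared host structure), makes every gene the
same length, gives every species the same pathway repertoire (real
missingness patterns are richer than `min_support` masking), and contains
no recombination, strain replacement, or within-host polymorphism.
Recovery results on this world demonstrate correctness of the machinery,
not properties of any real community.

A further estimator caveat: the sample CV of a heavy-tailed lognormal is
biased downward at realistic species counts (for a target CV of 1.2 at 40
species, the median per-pathway sample CV is near 1.0).  The generator's
enforcement is therefore tested on the log scale, where the sd estimator
is well-behaved, and the pipeline's measured CV is compared against the
sample CV of the generator's own targets.

## Numerical choices

* `(1 - e^{-x})/x` is evaluated with `expm1`, switching to a series below
  `x = 1e-8`; the curve is written as `1 - f_sel (1 - g)` so the neutral
  limit is exactly 1 in floating point.
* In the permutation engine the observed mean is accumulated with the same
  arithmetic as the null sums, so exchangeable-and-constant inputs tie
  exactly instead of flagging on rounding error; near-ties in p-value
  counting carry an absolute guard of 1e-12.
* Matrix rows and columns are sorted with C collation, all text output is
  UTF-8/LF with '.' decimals and 17-significant-digit floats, outputs embed
  the tool version, a hash of the analysis parameters, and the seed — and
  contain no timestamps or absolute paths — so a rerun at a fixed seed is
  byte-identical.
* Every stochastic routine takes an explicit seed and restores the
  caller's RNG state; the generator derives disjoint sub-seeds for tree,
  constraint and count streams.

## Known limitations

* One pathway per gene (multi-membership would double-count observations
  in the permutation nulls); one flat annotation level.
* No phylogenetically-corrected permutation scheme: species observations
  are not independent, which the Mantel-style regression quantifies but
  the exceptional-species test does not correct for.
* No codon-model ML estimation of dN/dS and no polymorphism (pN/pS)
  statistics; the two-parameter curve assumes a single effective selection
  class.
* Absolute selection coefficients are unidentifiable without a mutation
  rate; `d_star` is reported in dS units.
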