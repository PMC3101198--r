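---
title: "Linking extinction risk to diversification: methods and models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking extinction risk to diversification: methods and models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyloRisk)
```

## The problem

In floras dominated by recent evolutionary radiations — the Cape flora of
South Africa is the canonical case — extinction risk shows a paradoxical
structure: threat is strongly clustered taxonomically and phylogenetically,
yet species-level biological predictors of risk are weak, and the most
threatened lineages are the *young, fast-diversifying* ones rather than the
old, species-poor relicts familiar from vertebrates. phyloRisk implements
the analysis chain used to establish and interpret that pattern, against
IUCN Red List tables, dated phylogenies, and gridded occurrence data.

The mechanistic reading the toolchain is built to probe is peripatric
speciation: if new species arise as small peripheral isolates, then sister
species will differ sharply in range size, small ranges will attract
threatened Red List categories, and clades that have speciated recently
will carry many small-ranged, threatened species — with no species-level
trait needed to explain who is at risk.

## Red List semantics

Categories follow the ordered IUCN scale LC < NT < VU < EN < CR < EW < EX.
Two conventions coexist, as they do in practice:

* **binary**: VU and above is "threatened" (`is_threatened()`); EX counts
  as threatened in proportions;
* **ordinal**: a 0–5 linear score from LC = 0 to EW = 5
  (`threat_score()`); EX has no position on this scale and must be
  excluded from trait-style analyses, which is why `threat_score("EX")` is
  an error rather than a silent 6.

Data-deficient and not-evaluated codes are rejected at parse time: the
analyses assume assessed-only lists, and silently dropping DD species
would bias every proportion downstream.

### Status transitions and the tertile G-test

Given two Red List snapshots, each species present in both is scored +1 /
0 / −1 as its category rose, held, or fell; genus indices sum the species
values. To ask whether the most threatened taxa deteriorate fastest,
genera are ranked by their mean 0–5 score in the *older* snapshot, species
are pooled within the top and bottom thirds of that ranking, and each is
classified "increased" versus "unchanged or decreased". The default test
(`transition_gtest_counts()`) treats the top-tertile counts as a
goodness-of-fit against the proportions observed in the bottom tertile,
with G = 2·ΣO·ln(O/E) on 1 df. With the historical counts 43:44 (top)
against 28:62 (bottom) this framing gives G ≈ 12.61; the usual 2 × 2
independence framing gives ≈ 6.21 on the same counts and is available via
`framing = "independence"` but is not the default, because the
goodness-of-fit reading is the one consistent with the published value.
Ranking ties are broken lexicographically by genus name for determinism,
and genera entering the ranking with a single assessed species are
included but flagged in the output (`singleton_genera`).

## Taxonomic selectivity

`selectivity_test()` measures how unevenly threat is spread over higher
taxa: the statistic is the unweighted variance across taxa of the
proportion of threatened species (a size-weighted variant exists but is
non-default, matching the plain "variance across taxa" reading).
Significance comes from randomizing species membership among taxa with
taxon sizes held fixed; p-values use the (count + 1)/(n + 1) convention
throughout so a permutation p is never exactly zero. `flag_extreme_taxa()`
reports per-taxon two-sided randomization probabilities with no
multiple-testing correction — deliberately, since the historical analyses
reported raw randomization flags. The per-taxon randomization distribution
is hypergeometric in expectation, which the tests exploit as an exact
oracle on small cases.

## Phylogenetic signal

`blomberg_k()` implements Blomberg's K entirely through Felsenstein's
pruning algorithm: observed MSE₀/MSE from deviations about the
phylogenetically weighted mean and from the standardized contrasts, and
the Brownian expectation (tr(V) − n/(1ᵀV⁻¹1))/(n − 1) assembled from
pruning by-products (the sum of tip heights and the root-estimate variance
multiplier), so no covariance matrix is ever formed or inverted. The test
suite checks the pruning route against a dense GLS oracle to 1e-8 on all
fixture trees up to 12 tips, and against `ape::pic` and `picante::Kcalc`.

Because the threat metrics fed to K here are bounded (proportions, 0–5
scores), the parametric Brownian expectation is not trusted for inference:
the pipeline reports only the tip-randomization p
(`k_randomization_p()`, 1000 shuffles by default), while K itself is still
returned for tabulation. Polytomies are resolved to zero-length
bifurcations and nudged by 1e-8 × tree height, with a warning; trees must
be ultrametric to a relative 1e-6.

## Disparity through time

`dtt_profile()` computes, at each divergence time, the mean relative
disparity of the lineages present immediately before that time slice —
each lineage's subtree disparity divided by whole-clade disparity, with
single-tip subtrees contributing zero. The profile opens at exactly 1
(the root lineage holds the whole clade) and a terminal slice at relative
time 1 records the tip epoch. Disparity defaults to the mean squared
pairwise difference (`avg_sq`); mean absolute difference is available
because the historical description says only "mean pair-wise distance".
DTT is invariant to affine transformations of the trait under both
metrics, and values above 1 are reachable (the worked 4-tip example in the
tests evaluates to 1.5 after the root divergence).

Two null models bracket the observed profile:

* **Brownian** (`brownian_null_dtt()`): Gaussian increments along
  branches; the disparity ratio cancels the rate, so the mean curve is
  rate-free (asserted in tests by running σ² = 1 against σ² = 100).
* **Punctuated / peripatric** (`punctuated_null_dtt()`,
  `simulate_punctuated()`): at each divergence one daughter — chosen with
  probability ½ — takes the parental value *divided by* the asymmetry
  factor (the peripheral isolate is the smaller one), the other inherits
  the parental value; both then drift by a mean-zero normal deviate along
  their branches, and the reduced daughter additionally gains
  `trend` × (branch length) on the branch immediately following the split,
  modelling the isolate's range expansion before its next divergence.
  Values are floored at a small positive epsilon so range-like traits stay
  positive.

Parameter defaults are the published simulation settings: asymmetry
factor 2, drift s.d. 2, trend 0.3. The root value is not stated in the
source material; the default is 50 occupied quarter-degree squares, a
mid-scale starting range for a widespread ancestor (large enough that the
multiplicative asymmetry, not the additive drift, dominates the signal —
the regime the model is meant to describe). Two drift time-scalings are
implemented because the historical description does not fix one: the
default scales the drift s.d. by √(branch length), which makes the
factor → 1 limit Brownian-consistent; `drift_scaling = "per_branch"` draws
one unscaled deviate per branch (the literal reading). The printed
parameter values cannot disambiguate the two, so both are kept,
flag-selected.

Under the defaults the punctuated model leaves the expected late-burst
signature: the DTT curve sits above the Brownian mean over the final third
of relative time in well over 90% of replicates on 64-tip trees, and the
terminal disparity level rises monotonically with the asymmetry factor
(checked at 1.5, 2, 4).

## Diversification models

Net diversification rate is ln(richness)/age (my⁻¹). `fit_threat_glm()`
fits binomial logit GLMs with per-genus (threatened, non-threatened listed)
counts as the response; richness and rate are log transformed and age
square-root transformed before fitting, and two sensitivity weightings are
available (log listed records; listed-to-richness ratio). Monotypic genera
have rate 0, whose log is undefined, so they are dropped from rate models
with a reported count. Analyses default to endemic genera only: ages of
non-endemics are overestimated when their sister lineages are missing from
the tree, biasing rates downward. Marginal deviance for a predictor is the
extra share of null deviance explained when it joins the reduced model.
`partial_mantel()` controls threat–diversification associations for
phylogeny using √my patristic distances, with |xᵢ − xⱼ| as the
trait-to-distance convention and a one-tailed permutation p by default
(both are open conventions in the source material; both are flags).

## Geography

Genus occurrences are aggregated per quarter-degree cell
(`aggregate_cells()`: unweighted means over genera present). The headline
clumping test runs Moran's I on the residuals of threat regressed on log
genus count (`richness_corrected_threat()`), so that spatial structure in
sampling richness cannot masquerade as clumped threat. Weights default to
binary queen contiguity (8 neighbours) on the lattice — the common choice
for gridded floristic data; rook and row-standardized variants are flags.
The z-score and p use the randomization-null variance with expectation
−1/(n − 1); a permutation p is available and agrees with the normal
approximation within 0.02 on ~200-cell grids.

Correlations between per-cell fields (threat vs. diversification, threat
vs. habitat impact) use Pearson's r with the Clifford–Richardson–Hémon
degrees-of-freedom correction: pair covariances are pooled in integer
Chebyshev distance classes (default up to 10 cells), the variance of r is
estimated from the normalized sum of products of the two fields'
autocovariances, the effective sample size is 1 + 1/var̂(r), and
F = r²(n̂ − 2)/(1 − r²) is referred to F(1, n̂ − 2). The correction changes
only the significance, never r. Calibration (in the acceptance tests): on
independent but spatially smooth fields where the naive t-test rejects far
above nominal (> 15% at α = 0.05), the corrected test holds 3–8%; on white
noise the effective sample size recovers n within 10%.

## The synthetic generator

`synth_cape_like_dataset()` produces every input the pipeline consumes,
with the statistical couplings the analyses are designed to detect:

* ~200 genera (default) of 5–200 species (log-uniform richness), ages
  uniform on 1–30 my — so rate = ln(n)/age spans realistic Cape-like
  values;
* species range sizes log-normal, with median coupled *negatively* to the
  genus's standardized log diversification rate (fast radiators have
  small-ranged species) and a shared family effect (s.d. 0.8 on the log
  scale) that clusters threat within higher taxa;
* categories assigned from range by thresholds CR ≤ 1, EN ≤ 3, VU ≤ 10
  occupied cells — range size standing in for the dominant listing
  criterion;
* exemplar species-level clade trees from the forward birth–death
  simulator (birth 0.5, death 0.1) with punctuated range evolution on
  them;
* genus occurrence footprints as clustered blocks on a 40 × 40 lattice,
  and a habitat-impact field generated *independently* of threat by
  moving-average smoothing of white noise — emulating the situation where
  extinction hotspots do not track habitat transformation;
* paired Red List snapshots in which a species' probability of moving up
  a category increases with its genus's mean score in the first snapshot.

Everything is a pure function of (config, seed) — datasets written twice
from the same seed are byte-identical — and every output file round-trips
through the package's own readers. What the generator does **not**
emulate: real Cape phylogeny shape or clade sizes, real QDS geography,
observational error in Red List assessment, and any feedback from trait
values to speciation/extinction rates (topology is fixed when traits are
simulated, a stated limitation of the DTT comparison design). Passing
tests therefore demonstrate statistical correctness and calibration of the
machinery, not reproduction of any empirical Cape value — the published
data-dependent numbers would require the original floristic databases.

## Numerical choices and problem sizes

Ultrametricity tolerance 1e-6 × tree height; contrast standardization
refuses zero-length sister pairs and points to `resolve_polytomies()`;
permutation p-values are (count + 1)/(n + 1) everywhere; simultaneous node
heights are collapsed into one DTT slice deterministically; the
birth–death n-tip stop advances the clock by a uniform fraction of one
waiting time so the youngest cherry has positive terminal branches.

The shipped tests run at desk scale, chosen as the smallest sizes at which
each property is statistically decisive: 500-replicate calibrations for
the selectivity type-I error and the Clifford correction, 500 Brownian
traits on a 128-tip tree for the K expectation, 200 punctuated replicates
on a 64-tip tree for the late-burst check, 100 synthetic datasets of 200
genera for GLM sign recovery, and oracle-equivalence fixtures of 6–12 tips
where dense GLS algebra is exact.
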