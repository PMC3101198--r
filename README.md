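# phyloRisk

Phylogenetic and spatial analysis of plant extinction risk for floras
dominated by recent radiations. The package asks, and answers with
testable machinery, the questions behind the "cradle and graveyard"
pattern of threat: is extinction risk clustered in particular higher taxa?
Does it carry phylogenetic signal, or does it vary mostly between close
relatives? Is trait/range disparity concentrated near the present, as
peripatric speciation predicts? Are young, fast-diversifying genera the
threatened ones? And is the geography of threat explained by
diversification rather than habitat loss?

It is aimed at comparative biologists and conservation analysts working
with IUCN Red List tables, dated phylogenies (newick, branch lengths in
my), and gridded (quarter-degree-square) occurrence data.

## What it computes

* **Red List semantics** — ordered categories LC < NT < VU < EN < CR <
  EW < EX; binary threat (VU and above); the 0–5 ordinal score (EX
  excluded); genus status-change indices between two Red List snapshots;
  and the tertile transition G-test, G = 2·ΣO·ln(O/E) on 1 df, comparing
  deterioration in the most- vs least-threatened genera tertiles.
* **Taxonomic selectivity** — variance across taxa of the threatened
  proportion, with significance from randomizing species among taxa
  (sizes fixed), plus per-taxon enrichment/depletion flags.
* **Phylogenetic signal** — Blomberg's K via Felsenstein pruning
  (K = (MSE₀/MSE)obs / (MSE₀/MSE)exp, Brownian expectation K = 1), with
  tip-randomization p-values for bounded traits.
* **Disparity through time** — relative subclade disparity at each
  divergence time, against a Brownian null and a punctuated/peripatric
  null in which one daughter inherits the parental trait divided by an
  asymmetry factor, with drift and a range-expansion trend
  (defaults: factor 2, drift s.d. 2, trend 0.3).
* **Diversification models** — net rates ln(n)/age; binomial GLMs of
  threatened proportions against log richness, √age, log rate, with AIC,
  marginal deviance, two sensitivity weightings; partial Mantel tests on
  √my phylogenetic distances.
* **Geography** — per-cell aggregation; Moran's I (binary queen weights
  by default) on richness-corrected threat; Pearson correlation with the
  Clifford–Richardson–Hémon effective-degrees-of-freedom correction.
* **Synthetic data** — a seeded generator producing complete Cape-like
  datasets (birth–death trees, punctuated range evolution, range-based
  categories, family-clustered threat, autocorrelated habitat fields,
  paired snapshots) so the whole pipeline runs and calibrates without any
  external database.

## Worked example

```r
library(phyloRisk)

# The published transition counts: top tertile 43 increased : 44 not,
# bottom tertile 28 : 62. Goodness-of-fit framing, 1 df.
res <- transition_gtest_counts(c(43, 44), c(28, 62))
#> G = 12.61, p = 0.00038

# A fully synthetic Cape-like dataset, then the analysis chain on it:
ds <- synth_cape_like_dataset(synth_config(n_genera = 80,
                                           grid_dim = c(20, 20)), seed = 7)

selectivity_test(taxon_partition(ds$species, "family"),
                 n_rand = 999, seed = 7)
#> selectivity variance = 0.0845, p = 0.001

fit_threat_glm(ds$genus_summaries, "rate")
#> Binomial GLM of threatened proportion (80 genera, weighting: none)
#>          term estimate      se     z          p
#> 1 (Intercept)    1.944 0.08117 23.96 8.189e-127
#> 2        rate    1.889 0.06287 30.05 2.314e-198
#> AIC: 1236.92  null deviance: 2362.29  residual deviance: 979.399

k_randomization_p(ds$clade_trees$clade01, ds$clade_ranges$clade01,
                  n_rand = 999, seed = 7)
#> K = 0.059, randomization p = 0.663

g <- ds$grid
morans_i(richness_corrected_threat(g),
         lattice_weights(g$cell_row, g$cell_col))
#> Moran I = 0.369, z = 14.45, p = 1.2e-47

clifford_corrected_correlation(g$mean_threat, g$habitat_index,
                               g$cell_row, g$cell_col)
#> r = 0.103, n_eff = 66.4, p = 0.41   (naive n = 400)
```

Reading the numbers: threat is significantly uneven across families
(randomization p = 0.001) and strongly coupled to diversification rate
(positive rate coefficient — fast radiators carry more threatened
species, the planted coupling). The punctuated range trait shows *no*
phylogenetic signal (K ≈ 0.06, p = 0.66): speciational asymmetry puts the
variation between sister species, not between deep clades. Threat is
spatially clumped even after correcting for cell richness (Moran's
I = 0.37), while the habitat-impact field — generated independently of
threat — is correctly not significant once the Clifford correction
shrinks 400 autocorrelated cells to ~66 effective observations.

`run_pipeline()` chains all stages on one dataset and writes per-stage
CSV/JSON outputs plus a combined report.

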