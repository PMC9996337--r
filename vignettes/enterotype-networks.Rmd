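---
title: "Enterotypes and clinical-microbial networks: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enterotypes and clinical-microbial networks: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistical machinery it
implements: the models and their assumptions, the parameters that matter,
what the synthetic generator does and does not emulate, and the places
where the design was genuinely open and a choice had to be pinned.

## The pipeline and its assumptions

`entronet` analyzes a two-group 16S cohort in six stages. Each stage is a
small set of pure functions over plain matrices and data frames, so any
stage can be run, inspected or replaced in isolation.

**Preprocessing** assumes an integer sample × feature count table.
`filter_low_count()` removes features whose *total across samples* is
below 10 reads. The per-sample reading of that rule would empty most
sparse ASV tables, so the total-across-samples reading is pinned here and
in the tests; the boundary keeps a feature totalling exactly 10.
`rarefy()` subsamples without replacement to a fixed depth (default
20,000), the classical ecological treatment of unequal library sizes;
samples below the depth are dropped and listed, never padded, because
padding fabricates reads. Rarefaction is verified to conserve row sums
exactly and to be mean-unbiased for the underlying proportions.

**Diversity.** Shannon entropy uses natural logarithms — on gut
communities with a few hundred observed features this puts values in the
4–5 range rather than the doubled log2 scale. Pielou's evenness is
Shannon over `log(observed)` and is undefined (NA) for single-feature
samples. Faith's PD and the UniFrac distances require a rooted feature
tree; PD includes the root branch when the tree is rooted. The PERMANOVA
pseudo-F is computed directly from the distance matrix
(`[SS_b/(k-1)]/[SS_w/(n-k)]` with within-group sums of squared
distances), and its permutation p-value counts the observed labeling as
one permutation, `(1 + #{F* >= F})/(1 + n_perm)`, so p can never be 0.
The implementation is cross-checked against `vegan::adonis2` in the test
suite rather than delegated to it, so the two routes stay independent.

**Differential taxa.** The per-taxon screen uses the two-sided Wilcoxon
rank-sum test with tie correction and *without* continuity correction;
this makes the two-group p-value exactly equal to the Kruskal-Wallis
p-value, so the rank-sum screen and the LEfSe first stage cannot disagree
about significance. Raw p < 0.05 is the significance call (a
Benjamini-Hochberg column is emitted alongside for transparency, but does
not gate the call). The LEfSe stage is implemented for the two-class,
no-subclass case: samples are rescaled to one million each (the
counts-per-million convention that makes the log10 threshold of 2.0
meaningful), survivors of the Kruskal-Wallis screen enter 30 bootstrap
rounds of a one-component LDA on two-thirds subsamples, and each taxon's
effect is the mean of its share of the projected class separation
(`|w_f| * gap`) and its raw class-mean difference, averaged over rounds,
reported as `log10(max(effect, 1))`. The effect-size formula has several
variants in circulation; this one is pinned because it is monotone in
planted fold change (a property the tests enforce with Spearman > 0.9
across 20 single-taxon plantings) while keeping the conventional 2-5
score range. A tiny jitter regularizes the LDA against exact
collinearity.

**Enterotyping.** Genus profiles are compared with the Jensen-Shannon
*distance* (the square root of the divergence, base-2 logs) — the square
root form is a true metric, which PAM and the Calinski-Harabasz index
implicitly assume. Zeros are replaced by a pseudocount of 1e-6 and rows
renormalized; the tests verify the metric axioms on random profiles. PAM
is solved exactly by enumeration when there are at most 3000 candidate
medoid sets — BUILD+SWAP is a local search and can miss the optimum even
at n = 8, which the exhaustive-search oracle in the tests would flag —
and by `cluster::pam`'s BUILD+SWAP above that size. The number of
clusters is chosen by Calinski-Harabasz over k = 2..10 on the
principal-coordinate embedding of the JSD matrix (all positive-eigenvalue
axes), the canonical enterotype recipe. Between-class analysis centers
the genus matrix, eigen-decomposes the size-weighted covariance of class
centroids and projects all samples on the top min(k-1, 2) axes; the
projection algebra is pinned by an identity test. Cluster labels come
from the classical driver panel (Bacteroides, Prevotella, Ruminococcus):
each cluster is named for the panel genus with the highest median
abundance inside it.

**Clinical statistics.** The battery dispatches on declared variable
kinds. Categorical variables get the Pearson chi-square without
continuity correction, switching to Fisher's exact test when any observed
cell is ≤ 5 — "any cell ≤ 5" is the pinned reading of the usual
small-sample rule. Percentages are compared with the *pooled*
two-proportion z-test; pooled rather than unpooled because the pooled
statistic squares exactly to the 2×2 chi-square, so the two entry points
can never disagree (an identity the tests check on random tables; the
unpooled variant remains available behind a flag). All tests are
two-sided. Propensity matching fits a logistic model on age and BMI and
matches greedily 1:1 without replacement in descending score order —
greedy rather than optimal because the diagnostics of interest are the
matched count and the standardized mean differences, both of which the
function reports, and greedy matching is transparent about both.
Missing values are handled pairwise-complete throughout.

**Networks.** The correlation panel holds the top 50 genera by mean
relative abundance, the encoded clinical variables (binary facets and
group status as 0/1, counts and continuous as numbers; unordered
categoricals are excluded since Spearman needs an ordering), and the
enterotype as its integer label. The ordinal encoding of the enterotype
is a deliberate, documented compromise: it allows a signed correlation
between enterotype membership and its driver genera, at the price of
imposing an arbitrary order on cluster labels; the panel metadata carries
this caveat. Spearman uses average ranks and the t-approximation for p
(adequate in the n ≈ 42 regime); Benjamini-Hochberg runs jointly over
*all* unique pairs — genus-genus, genus-trait, trait-trait — which is
the conservative reading when the adjustment family is ambiguous. An
edge needs adjusted p < 0.05 *and* |ρ| ≥ 0.35, boundary included.
Betweenness is summed over unordered pairs (the ordered-pair reading
would exactly double every score on an undirected graph and break the
canonical path example `BCI(b) = 1` on a-b-c). HITS hub/authority scores
are computed by power iteration with L2 normalization per round and
rescaled so the maximum hub and authority equal 1, putting reported
indices on [0, 1]; the classical L2 eigenvector normalization is
available, and on a degenerate top eigenspace (disconnected components
with tied eigenvalues) the iteration limit depends on initialization,
which is why the eigenvector cross-check in the tests restricts itself to
simple-eigenvalue cases.

## The synthetic generator

The generator emulates the *structure* such a study assumes, not any real
cohort:

* **Counts** are Dirichlet-multinomial per sample: a genus-proportion
  vector drawn from a Dirichlet with mean equal to the community
  template and concentration 50, then a multinomial at a depth drawn
  uniformly from 25,000-30,000. Concentration 50 gives realistic
  overdispersion — rare genera are strongly zero-inflated, as in real 16S
  data — while keeping community types recoverable.
* **The genus panel** holds 94 genera: 30 named gut genera with means
  echoing a typical Western gut profile (Faecalibacterium, Bacteroides
  and Roseburia near 14-15% each, a long tail below 1%), and uniform
  filler genera. All lineages are synthetic scaffolding for the
  taxonomy-aware steps.
* **Community types.** Three templates whose drivers (Prevotella,
  Ruminococcus, Bacteroides) are boosted by a factor of 8 and
  renormalized. The boost is the one calibrated parameter: it was chosen
  once so that the JSD/PAM/Calinski-Harabasz pipeline recovers k = 3 in
  at least 90% of seeds at n = 42, the property the acceptance tests
  enforce. Membership is drawn per sample with group-conditional
  probabilities that over-represent community type 2 in the MUD group.
* **Clinical variables** are Bernoulli (binary facets, per-group
  prevalences), Poisson (counts) or Normal (continuous). The default
  panel mirrors a stimulant-use cohort: loss-of-control, craving,
  tolerance and withdrawal facets common in the MUD group and rare or
  absent among casual users.
* **Planted associations** use a Gaussian copula: the genus's abundance
  ranks are mapped to normal scores `u`, and the trait's latent is
  `r*u + sqrt(1-r^2)*e` with `r = 2*sin(pi*rho/6)`, the exact relation
  between a bivariate normal's Pearson parameter and its population
  Spearman. Continuous traits take the latent directly; count traits are
  discretized onto an equiprobable ordinal grid (default 12 levels, a
  0-11 score), which attenuates the realized Spearman by only about 1%.
  Binary traits are refused for exact planting — dichotomization
  attenuates the coefficient unpredictably — and only a documented
  attenuated variant (latent thresholded at the trait's prevalence
  quantile) is offered behind `allow_binary = TRUE`.

**What passing tests do and do not show.** The generator produces
compositional, overdispersed, zero-inflated counts with planted cluster
and correlation structure — the features the pipeline's statistics
actually consume. It does not emulate sequencing error, chimeras,
taxonomy misassignment, longitudinal dynamics, or covariance between
clinical facets beyond the group labels; recovery results on synthetic
data therefore validate the *method implementations*, not any biological
claim about a real cohort.

One limitation deserves emphasis: planting an association against the
*realized counts* of a rare genus (mean abundance well below
1/concentration) attenuates the recovered Spearman, because a large
fraction of samples tie at zero counts and ties compress ranks. The
recovery harness `planted_recovery()` therefore plants against the
continuous Dirichlet layer (the gamma-distributed proportions underlying
the counts), where the copula identity holds exactly; the attenuation on
realized counts is visible and expected if one correlates planted traits
with rarefied counts of a 0.4%-abundance genus.

## Numerical choices and degenerate inputs

* JSD pseudocount 1e-6 (renormalized); JSD of identical rows is exactly 0
  and of disjoint supports approaches 1.
* PAM ties break toward the lowest sample index; both solver paths are
  deterministic, and the `seed` argument exists only for interface
  symmetry.
* Calinski-Harabasz is undefined at k = 1 and k = n; `optimal_k()` clips
  the range and refuses an all-zero distance matrix.
* HITS converges when the largest score change drops below 1e-10;
  exceeding 1000 iterations is an error carrying the residual, not a
  silent truncation.
* Zero-margin contingency tables, empty groups, zero-total samples and
  missing tree tips are errors naming the offending object; features
  without a lineage are retained with a warning.
* All writers produce files their paired readers accept unchanged; the
  readers reject malformed cells rather than coercing them.

## Problem sizes

The test suite and the recovery script run at the cohort's own scale
(n = 42, 94 genera) where the study conditions demand it — cluster-number
recovery and ARI use 100 seeds, planted-correlation recovery 200
replicates — and at reduced oracle scales elsewhere (exhaustive k-medoids
at n = 8, path-enumeration betweenness on 10-node graphs, Fisher
enumeration at n ≤ 30, PERMANOVA type-I at n = 16 with 199 permutations ×
1000 simulations). These sizes are the package's choices for keeping the
oracles exact and the simulations well-powered.
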