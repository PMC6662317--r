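---
title: "Trait-based diversity indices and null-model assembly inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trait-based diversity indices and null-model assembly inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fdassembly)
library(dplyr)
```

## The question the package answers

When a bird community assembles in a disturbed habitat — say a cacao
agroforest carved out of Atlantic-forest landscape — two deterministic
processes leave opposite fingerprints on the traits of the species that
coexist there. *Niche filtering* admits only species whose phenotypes suit
the environment, so co-occurring species are more similar than a random
draw from the regional pool. *Limiting similarity* (competition) excludes
ecologically redundant species, so survivors are more different than
random. If neither dominates, trait structure is indistinguishable from a
random draw.

`fdassembly` operationalizes this inference: it computes functional
diversity indices on mixed (binary + continuous) trait tables,
standardizes them against a trait-shuffle null model, and tests habitat
contrasts. A synthetic community generator with *known* assembly rules
closes the loop: every stage of the pipeline can be validated against
ground truth.

## The trait table and functional space

Species are described by one continuous trait (mean body mass, grams) and
25 binary foraging traits — food types, foraging strata/substrates,
foraging methods, activity period and mixed-flock participation — declared
in an explicit schema (`default_trait_schema()`) rather than inferred from
the data, because silently misreading a 0/1-coded continuous column is the
main I/O hazard in this kind of table. All traits carry equal weight.

Pairwise functional dissimilarity is the Gower coefficient
$$d_{ij} = \frac{1}{T} \sum_{k=1}^{T} \delta_k(i,j),$$
with $\delta_k = |x_{ik}-x_{jk}|$ for binary traits (symmetric mismatch)
and $\delta_k = |x_{ik}-x_{jk}|/\mathrm{range}_k$ for body mass. Two
deliberate choices:

* **Symmetric binary treatment.** Shared absence of a foraging capability
  is treated as similarity. These traits are capabilities, not rare-state
  presences, so double zeros are informative; an asymmetric (Jaccard-style)
  variant is available via `binary = "asymmetric"`.
* **Pool-level ranging.** The body-mass range is computed once on the full
  regional pool and reused for every species subset, so distances for,
  say, the insectivore subgroup are directly comparable with the full
  community — a subgroup's distance matrix is exactly a submatrix of the
  pool matrix. Body mass enters untransformed by default; `log_mass =
  TRUE` switches to log10 mass, and results will differ.

From the distance matrix the package builds the two geometric objects the
indices need: a UPGMA (average-linkage) dendrogram, with species sorted
lexicographically beforehand so tied merges resolve deterministically, and
a Euclidean embedding by principal coordinates. Gower matrices on mixed
traits are usually non-Euclidean, which makes some PCoA eigenvalues
negative; the Cailliez correction adds the smallest constant $c$ to all
off-diagonal dissimilarities that removes them. All axes with eigenvalue
above $10^{-8}$ are retained, so the corrected geometry is preserved
exactly rather than truncated to an arbitrary axis count. A convenient
consequence used internally: Euclidean distances in the full corrected
space are simply $d_{ij} + c$, so null-model replicates never need the
coordinates at all.

## The four indices

For a community with species set $S$ and relative abundances $p_i$:

* **FD** — the total branch length of the UPGMA dendrogram of the
  community's species, excluding the segment above the root; presence-based
  functional richness. The dendrogram is *re-clustered per community* from
  the pool submatrix (the convention matching a per-site tree-height
  computation); pruning a single pool dendrogram instead is a different
  estimator and is not the default. Branch length is the edge sum
  $\sum (h_{\mathrm{parent}} - h_{\mathrm{child}})$, which equals the
  classic tree-height convention (the test suite cross-checks against
  `vegan::treeheight`). $S = 1$ gives FD = 0.
* **FEve** — evenness of abundance along the community's minimum spanning
  tree in corrected trait space: for each MST edge $l$ joining $i,j$,
  $EW_l = \mathrm{dist}(i,j)/(p_i+p_j)$, $PEW_l = EW_l/\sum EW$, and
  $$\mathrm{FEve} = \frac{\sum_l \min(PEW_l, \tfrac{1}{S-1}) - \tfrac{1}{S-1}}
    {1 - \tfrac{1}{S-1}}.$$
  The formula degenerates at $S < 3$; such communities get `NA`, never 0,
  and are dropped pairwise from FEve contrasts with a logged count.
* **Rao's Q** — $Q = \sum_i \sum_j d_{ij} p_i p_j$, the expected
  dissimilarity between two random individuals.
* **Simpson** — the taxonomic counterpart: Rao with all distances set
  to 1.

Q and Simpson are reported on the *equivalent community* scale through the
Jost correction $1/(1-x)$: the number of equally abundant, maximally
distinct species yielding the same index value. FEve, Rao and Simpson are
abundance-weighted; FD is presence-only.

## The null model and SES

Each landscape is its own regional pool: the species recorded anywhere in
it. A null replicate reshuffles the species *names* over the unchanged
trait rows of that pool, then recomputes every index with the community
compositions and abundances untouched. This conserves trait covariance,
the phenotype set, occupancy rates, richness, abundance distributions and
beta diversity — the only thing randomized is which phenotype a name
points to. With 999 replicates (the default; tests use 199 for speed):

$$\mathrm{SES} = \frac{\mathrm{observed} - \overline{\mathrm{null}}}
  {\mathrm{sd}(\mathrm{null})}$$

SES < 0 indicates clustering (filtering), SES > 0 overdispersion
(limiting similarity). Whether a habitat's communities deviate from 0 is
tested per habitat × subgroup × index with one-sample *t* tests — the
per-habitat reading matches how the assembly marks are reported under
habitat-level bar charts.

Two design points were genuinely open:

* **Subgroups inside the null.** Analyses are repeated for forest
  specialists (high forest dependency), habitat generalists (low;
  medium-dependency species belong to neither), frugivores/granivores
  (fruits and/or seeds in the diet) and insectivores. The default null
  shuffles over the *full* landscape pool and re-derives subgroup
  membership inside each replicate — that is what reshuffling the row
  names of the whole trait matrix literally does, and it preserves the
  conservation properties above. `shuffle_within_subgroup = TRUE` gives
  the alternative (membership held fixed) for sensitivity analysis.
* **Degenerate nulls.** If every pool phenotype is identical the null sd
  is 0 and SES is undefined; it is reported `NA` with a warning, not
  coerced.

Every (landscape, index, subgroup) combination draws from its own RNG
stream derived from the master seed by a deterministic hash, so adding a
subgroup or index to a config never perturbs existing results, and a rerun
of `run_pipeline()` with the same config is byte-identical.

## Habitat contrasts and supporting tests

Forest vs agroforestry differences in richness, Jost-corrected Simpson,
and the three SES metrics are tested with two-sided permutation *t* tests
on the difference in group means. When $\binom{n_1+n_2}{n_1}$ does not
exceed `n_iter` (default 100,000) the enumeration is exhaustive and the p
value exact — this covers both default designs (12+6 gives 18,564
arrangements, 4+4 gives 70); otherwise Monte-Carlo sampling with the
add-one rule keeps p strictly positive. With five subgroups and three
indices there are 15 SES comparisons per landscape, numbered explicitly in
the contrast table; only p < 0.01 is flagged conclusive (0.05 and 0.10 are
annotation tiers), and no formal FDR correction is applied — the stringent
threshold is the multiplicity control.

Spearman correlations between taxonomic (S, Simpson equivalents) and
functional (SES) metrics check that the functional signal is not simply
taxonomic diversity in disguise, and Moran's I — inverse-distance weights,
row-normalized, normal-approximation p, expectation $-1/(n-1)$ — checks
for spatial autocorrelation; note the 4+4 landscape leaves little power
there.

## What the generator emulates — and what it does not

`simulate_landscapes()` produces a regional pool and a two-landscape
survey mirroring the motivating study system's structure: landscape A with
12 forest and 6 agroforestry sites, landscape B with 4 and 4. Generator
defaults, chosen once as field-realistic values:

| Parameter | Default | Why |
|---|---|---|
| pool size | 150 species | a plausible regional bird pool for desk-scale replication studies |
| binary traits | 25, prevalence ~ Beta(2, 2) | mid-range prevalences with variation across traits |
| body mass | lognormal, meanlog log(35), sdlog 1.2, clipped to 2–2172 g | right-skewed masses spanning the hummingbird-to-large-bird range |
| forest dependency | high/medium/low at 0.3/0.4/0.3 | all three classes well represented so SPE and GEN subgroups are non-trivial |
| richness per site | Normal(30, 5), min 5 | of the order of point-count richness per site in such surveys |
| abundances | lognormal counts, meanlog log(5), sdlog 1 | few abundant, many rare; independent of traits by default |
| site coordinates | uniform in 10 km boxes, ≥ 200 m apart | transect-like minimum spacing |
| filtering strength σ_f | 0.1 Gower units | inclusion odds fall by half ~0.12 Gower units from the optimum — strong, unambiguous filtering |

Assembly per habitat is neutral (uniform draw), filtering (inclusion
probability $\propto \exp(-g_i^2 / 2\sigma_f^2)$, where $g_i$ is the Gower
distance to a habitat optimum drawn as a real pool phenotype so $\sigma_f$
is interpretable in Gower units), or limiting similarity (greedy max-min
spacing). Species rejected by the structural constraints (every species
needs a food type and a foraging stratum) are redrawn, so generated pools
always validate.

The generator deliberately does **not** emulate: phylogenetic or other
trait covariance structure, trait-linked abundances (available as an
option), detection error in point counts, spatial autocorrelation (none is
injected, so Moran's I should be null — a positive control requires the
optional gradient), or real bird taxonomic structure. Passing the
calibration and recovery tests therefore shows the *statistical machinery*
is sound under its own assumptions, not that any particular field dataset
will behave this way.

## Validation studies and problem sizes

Two replicate studies ship with the package and are rerun by
`scripts/acceptance.R`:

* `neutral_calibration()` — 50 all-neutral surveys at the default layout,
  199 nulls: mean SES per index should sit within ±0.15 of 0 and the
  per-habitat one-sample *t* rejection rate at α = 0.01 within binomial
  bounds of nominal.
* `scenario_recovery()` — 25 surveys with filtering (or limiting
  similarity) imposed on agroforestry only, evaluated in the 12+6
  landscape: agroforestry sesFD/sesRao should be significantly negative
  (positive for limiting similarity), forest null, and the habitat
  contrast conclusive. The 4+4 landscape cannot reach p < 0.01 by
  exhaustive permutation (the smallest two-sided p over 70 arrangements is
  ≈ 0.029), which is why recovery is scored in the larger landscape — a
  useful reminder that the stringent threshold costs power in small
  designs.

These sizes (199 nulls, 50/25 replicates) are the package's validation
design; a real analysis should use the 999-null default.

## Known limitations

* FD by per-community re-clustering and FD by pruning a pool dendrogram
  are different estimators; only the first is the default here
  (`fd_index()`), and comparisons across studies should note which was
  used.
* The Jost correction is undefined at index values of 1 (saturation);
  this is raised as an error rather than clamped.
* Monte-Carlo permutation p values are bounded below by 1/(n_iter + 1);
  exhaustive mode removes this floor only when enumeration is feasible.
* With 199 nulls the SES denominator is itself noisy (~5% sd inflation);
  the calibration study absorbs this, but single-site SES values should
  not be over-read.

```{r example, eval = FALSE}
# A complete run at analysis-grade settings:
sim <- simulate_landscapes(scenario_config(
  assembly = list(forest = "neutral", agroforestry = "filtering"),
  seed = 2026
))
report <- run_pipeline(sim$traits, sim$communities,
                       pipeline_config(n_null = 999, seed = 2026))
tidy(report)      # habitat contrasts with assembly tests
glance(report)    # one-row summary
autoplot(report)  # SES bars with significance marks
```
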