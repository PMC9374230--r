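---
title: "Methods: quantitative analysis of quadrat-based vegetation surveys"
author: "phytosurvey"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative analysis of quadrat-based vegetation surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phytosurvey)
```

## The survey design this package models

A quadrat-based vegetation survey records, at each of several sites, which
plant species occur in a fixed number of sampling frames (quadrats) and how
many individuals of each. Because plants of different stature need different
frame sizes, the three habit layers use different quadrat areas — 1 m² for
herbs, 25 m² for shrubs, 100 m² for trees (the `layerAreas` of a
`SurveyDataset`). The reference design emulated throughout the package is 12
sites with 4 quadrats each (48 quadrats), a regional pool of about 120
species, and per-site species counts between 18 and 45.

The canonical input is the long (tidy) quadrat CSV — one row per (site,
quadrat, species) — because that is how field data are recorded; the sites ×
species `CommunityMatrix` is always derived by pooling
(`buildCommunityMatrix`). Absences are implicit. A wide site × species CSV is
accepted as an explicit alternative import (`readWideCommunityMatrix`) for
data already pooled, at the price of losing quadrat-level statistics.
Species matching is exact after whitespace normalisation and case-folding;
synonymy resolution is out of scope.

Survey protocols of this kind are often internally ambiguous about the number
of quadrats per site ("four quadrats" vs "three quadrats on four points");
the package infers the count from distinct quadrat identifiers, with an
override argument, and defaults the generator to 4 per site so the 48-quadrat
total holds.

## Phytosociological statistics

For every (site, species) pair, `computePhytosociology` computes the seven
classical quadrat statistics. Frequency is the percentage of the site's
quadrats containing the species; density is individuals per 100 m², with the
denominator the area actually sampled for the species' *own* layer (herb
counts over herb-quadrat area, and so on) — with mixed quadrat sizes there is
no single "total area sampled" that is meaningful across layers. Composition
is the species' share of all individuals at the site.

Relative frequency and relative cover are each value as a percentage of its
site total, so each sums to 100 within a site. Relative density uses the
classical area-free form — individuals of the species over individuals of
all species × 100 — which coincides with the density-share within a single
layer but is the form that remains meaningful across layers with unequal
quadrat areas.

Cover has two recording traditions and both are implemented, selected by
`coverSource`:

* `class_midpoint` (default): visual Daubenmire classes 1–6, converted to
  percent by the fixed midpoints 2.5, 15, 37.5, 62.5, 85, 97.5 (class
  boundaries 0–5, 5–25, 25–50, 50–75, 75–95, 95–100) and averaged over the
  site's quadrats, absences counting as zero cover;
* `intercept`: line-intercept lengths over a transect denominator
  (`transectLength` per site; if unspecified the site's total intercept is
  used, making cover coincide with relative cover).

A species with no cover information has `NA` cover and is excluded from the
relative-cover normalisation: missing is not zero abundance.

## Alpha diversity

Per site (all quadrats and layers pooled): Shannon `H = -sum p log p` in
natural-log units — the evenness convention `J = H / ln S` fixes base *e* —
Simpson's index (Gini–Simpson `1 - sum p^2` by default, the convention of the
common community-ecology software; the dominance form is available), Pielou
evenness, and a richness index. The richness formula is deliberately a
mandatory, recorded choice (`margalef_ln`, `margalef_log10`, `menhinick`):
surveys in this literature print "richness" computed with either logarithm
base, and the two differ by a factor of ln 10 ≈ 2.30, so `diversityTable`
refuses to leave the method implicit. `margalef_ln` is the default.

Diversity is compared across soil-texture groups with the two-sided
Wilcoxon rank-sum test (`wilcoxonRankSum`, wrapping `stats::wilcox.test`).
In `auto` mode the exact distribution is used when the combined sample size
is at most 12 and the data are tie-free — small enough to be instant and
large enough to cover pairwise comparisons among a dozen sites — otherwise
the normal approximation with tie and continuity corrections. Fully tied
data (zero-variance) return p = 1: no evidence of a shift.

## Beta diversity and ordination

The analysis sequence is transform, then distance, then inference:
`log10Plus1` (the zero-safe reading of a log10 transform on counts), then
Bray–Curtis dissimilarity `BC = sum|x - y| / sum(x + y)` with all-zero
species columns pruned, then:

* **PERMANOVA** (`permanova`): one-way design only, soil texture as the
  single factor. `SS_total = (1/N) sum_{i<j} d_ij²`, `SS_within` the
  analogous within-group sum weighted by group size, pseudo-F =
  `(SS_between/(a-1)) / (SS_within/(N-a))`. Significance comes from freely
  permuting whole rows; p = (#{F_perm ≥ F_obs} + 1)/(n_perm + 1), ties
  counted as at least as extreme (conservative). The default is 999
  permutations and the seed argument is mandatory — a permutation p without
  a recorded seed is not reproducible. With perfectly separated groups
  (SS_within = 0) the observed F is infinite; permuted statistics count as
  extreme only when they are also degenerate.
* **PCoA** (`pcoa`): Gower double-centring `B = -1/2 J D² J`,
  eigendecomposition, coordinates scaled by the square root of positive
  eigenvalues. Axes with |eigenvalue| below 1e-10 × the largest are dropped
  as numerical zeros. Bray–Curtis matrices are generally non-Euclidean;
  the negative-eigenvalue mass is always reported, and the Cailliez
  correction (smallest additive constant making the off-diagonal distances
  Euclidean, found as the largest real eigenvalue of the standard 2n × 2n
  companion matrix) is available when a fully Euclidean embedding is wanted.

Constrained ordination (CCA/RDA), environmental-vector fitting and
dispersion (PERMDISP) tests are out of scope.

## Parameter associations

`correlationTable` computes lower-triangle Pearson correlations over the
(site, species) rows of the phytosociology table pooled across sites — the
unit of analysis is recorded in the run report because survey papers rarely
state it. The test is the usual `t = r sqrt((n-2)/(1-r²))` on n − 2 degrees
of freedom (via `stats::cor.test`), flagged `**` for p ≤ 0.01 and `*` for
0.01 < p ≤ 0.05. No multiple-testing correction is applied, matching the
descriptive use of these tables.

## Quantitative SWOT scoring

Indicators are weighted by perceived importance within four groups
(strengths/weaknesses internal, opportunities/threats external). The
importance coefficient of indicator *i* is `IC_i = W_i / sum(W)` with the
denominator the total over **all** indicators of all four groups — this is
the only reading under which a published 29-indicator table's per-indicator
coefficients (100 → 0.05, 90 → 0.04, …, 30 → 0.01 at total weight 2070) are
all reproduced after rounding. Exact coefficients sum to 1 and group
subtotals partition it; reported cells are rounded half-up at 2 decimals
(`roundHalfUp`, since base R rounds half-even) while all arithmetic uses
unrounded values. The published table's per-group "subtotal" weight cells
follow a weight-sum/10 display convention, reproduced as
`subtotal_weight_reported` and never used in IC arithmetic. Two of the
published subtotal coefficients (strengths 0.42, threats 0.17) are not
consistent with the formula that reproduces every other printed value (it
gives 0.41 and 0.16); the package reports the computed values and the run
report notes the discrepancy rather than silently matching. Weights outside
the nominal 100–1000 scale are accepted with a warning — the published table
itself uses 30–100.

## The synthetic survey generator

`simulateSurvey` exists so that every stage is testable without the (never
deposited) field data. It emulates: the 12 × 4 quadrat design; a 120-species
pool with the 89/16/15 herb/shrub/tree mix (largest-remainder allocation, so
the default pool matches exactly); per-site richness uniform on 18–45; a
soil assignment of 8 loam, 2 clay-loam, 1 sandy-loam, 1 sand sites; and
log-normal species abundances (meanlog 1.0, sdlog 0.8).

Design choices that matter for what the tests can show:

* **Texture signal.** Each pool species is assigned one preferred texture
  block; when a site's texture matches, that species' sampling weight is
  multiplied by `exp(effectSize)`. `effectSize = 0` gives a fully
  exchangeable null — the basis of the PERMANOVA type-I calibration — and
  the signal is monotone in `effectSize`, giving a power check at
  `effectSize = 3`. This two-block tilt is the simplest mechanism with a
  tunable, monotone multivariate signal; it is not a niche model.
* **Abundance structure.** The marginal log-abundance of a present species
  is Normal(meanlog, sdlog), split equally (sdlog/√2 each) between a
  persistent species effect and site-level noise. The species effect gives
  the pool a stable commonness ranking; as `abundanceSdlog → 0` communities
  become uniform and Pielou evenness approaches 1, which the tests use as a
  parameter-recovery check.
* **Frequency–density coupling.** Site abundances are scattered over
  quadrats multinomially, so a species' frequency rises mechanically with
  its abundance — reproducing the strong relative-frequency ×
  relative-density association such surveys report.
* **Cover realism.** The Daubenmire class of a pool species ranks a latent
  score with a 0.5 loading on the species abundance effect, the rest
  observational noise: visually estimated cover tracks abundance only
  loosely (cover follows plant stature as much as plant number), which is
  why the density–cover association is markedly weaker than the
  frequency–density one, as in published correlation tables.
* **Soil covariates** are drawn near typical reported values for such
  riverine sites (pH ~ N(8.2, 0.2) truncated to physical range,
  K ~ N(130, 25) ppm, organic matter ~ N(0.7, 0.1) %, …). They validate
  through the same rules as read data but carry no built-in relationship to
  composition beyond texture.

One run seed drives separate derived sub-streams per stage, so e.g. soil
covariates can be regenerated without re-drawing community composition, and
the same seed and configuration yield byte-identical output files.

What the generator does **not** emulate: spatial autocorrelation among
quadrats, temporal/seasonal turnover, realistic taxonomy or trait structure,
zero-inflation beyond what the occupancy draw induces, and
abundance–environment gradients other than the single texture tilt. Passing
tests therefore demonstrate correctness of the computations and calibration
of the inference under exchangeable nulls — not that real riverine
vegetation satisfies those assumptions.

The deterministic `syntheticChecklist` is a separate, clearly synthetic
stand-in for a published species checklist that is not machine-readable: it
reproduces only the marginal counting structure (120 species, 105 genera, 51
families; 96/17/6/1 dicots/monocots/pteridophytes/bryophytes; 89/16/15
habits), with synthetic names.

## Verification strategy and problem sizes

The test suite checks every statistic against an independent route: direct
summation oracles for the indices, full enumeration for the exact Wilcoxon
test (every tie-free rank configuration up to combined n = 8), `vegan`
(`vegdist`, `adonis2`, `diversity`) and `ape::pcoa`/`cmdscale` as external
cross-checks for the beta-diversity machinery, and closed forms (uniform
communities, equilateral triangle, planar point sets reconstructed to 1e-8)
for the ordination. The PERMANOVA null calibration uses 500 generator
replicates at 199 permutations each with rejection at α = 0.05 required to
fall in [0.03, 0.07], and 100 replicates at `effectSize = 3` for the power
comparison — sizes chosen to put the binomial error on the estimated
rejection rate near one percentage point while keeping the default test run
around half a minute.

## Known limitations

* One-way PERMANOVA only; no covariates, interactions, strata, or
  dispersion diagnostics.
* The intercept cover path needs an externally supplied transect length to
  be an absolute cover; otherwise it degrades gracefully to a relative
  measure.
* Richness indices depend on a formula choice the surrounding literature
  often leaves implicit; the package forces the choice but cannot recover
  which formula an external table used.
* Pearson associations on percentage-normalised rows are descriptive; the
  within-site sum constraint induces mild negative dependence the
  t reference distribution ignores.
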