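---
title: "Methods: harmonizing multi-site NPP databases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: harmonizing multi-site NPP databases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nppdb)
library(dplyr)
```

Field estimates of terrestrial net primary production (NPP) are reported
component by component — stem increments, litterfall, fine-root production,
herbaceous peak biomass — with methods that differ widely in accuracy, over
measurement series of one to sixteen years, and in units that mix dry mass
and carbon. A multi-site compilation is only usable for model benchmarking or
climate regression if those pieces are put on a common scale, summed in a
defensible hierarchy, and accompanied by an uncertainty that reflects *how*
each number was measured. This vignette describes the models and conventions
this package implements, the choices that were genuinely open, and what the
synthetic test data do and do not demonstrate.

## The data model

A database is a set of twelve tables keyed by `site_id`: site information,
component-level NPP estimates, three methodology tables (aboveground,
belowground, total), stored aggregate levels, and six ancillary tables
(monthly climate normals among them). Values are in grams of dry mass per
square metre per year; records reported in grams of carbon are divided by
their study's carbon-content fraction at load time. No default carbon
content is imputed — a carbon-unit record without an explicit factor is a
validation error, because inventing a factor would fabricate data.

Validation is total: every row is either accepted or lands in a structured
issue report (never silently dropped). Components are harmonized onto a
closed vocabulary (stems, branches, foliage litter, extra litter,
reproductive material, herbs, shrubs, non-vascular plants, understory, fine
and coarse roots, herbivory losses, rapidly decomposed tropical leaf litter,
volatile/exudate fluxes, and direct total NPP), with the source's original
label preserved verbatim.

## Hierarchical summation and gating

Site-level aggregates are computed on an eight-level hierarchy: herb+shrub
ANPP; non-tree ANPP (adding non-vascular vegetation); wood ANPP
(stem + branch); total litterfall ANPP (foliage + extra litter); tree ANPP
(wood + litterfall); BNPP (fine + coarse roots); total NPP 1
(tree + non-tree + BNPP); and total NPP 2, which adds herbivory losses,
reproductive material when it is not already inside the litterfall
collection, and — in tropical forests only — leaf litter lost to rapid
decomposition.

The central rule is *gating*: a level gets a value only when every
constituent is either measured or verified absent at the site. An
unmeasured, unflagged component makes the level `incomplete`, with no value
emitted; no gap-filling is attempted. Three applicability conventions keep
the single hierarchy workable across biomes:

* In non-forested biomes all root production is assumed to be contained in
  the fine-root estimate, so an unreported coarse-root component does not
  block the BNPP level.
* In biomes without a tree layer (grassland, cropland, tundra, peatland),
  unreported tree components are treated as not applicable rather than
  unknown. A level whose constituents are all absent or not applicable is
  reported `not_applicable` and contributes zero to the levels above it.
  This per-component convention (rather than switching the whole tree branch
  at once) keeps gating *monotone*: adding a measurement or an absence flag
  can never flip a level from complete to incomplete.
* Understory production in forests satisfies both the herb and the shrub
  slot, since overstory is exactly the tree-ANPP branch.

Reproductive material is counted exactly once: a record flag says whether it
was reported inside the extra-litter collection, and conflicting flags raise
a double-count error. Whether extra litter includes reproductive material is
source-dependent, so the check is driven by that per-record flag rather than
by a global rule. Sites whose above- and belowground campaigns used
different years or methods are still summable on the site-mean view but
carry a `mixed_campaign` provenance stamp on every level.

A separate completeness audit compares each site against the main/minor
component expectations of its ecosystem type (boreal, tropical and other
forests, fruit plantations, grassland, cropland, peatland/tundra with and
without substantial non-vascular vegetation, and woodland savanna): missing
*main* components mean the site should be excluded from harmonized
analyses; missing minor ones are informational. Coarse roots are classed
minor even in woody biomes because they are nearly always derived from
aboveground components rather than measured.

## Method-specific uncertainty

Uncertainty is attached per measurement, not copied from source studies,
because source-reported standard deviations are incomparable across
methodologies. The model has three ingredients:

1. **Biome spread** `P`: half the 90th–10th interpercentile range of the
   site-level values of a component class (ANPP, BNPP, TNPP) within a biome,
   derived from the database itself. Percentiles interpolate linearly
   between order statistics (`stats::quantile` type 7, the common
   statistics-software default); the convention is configurable
   (`"nearest"` uses type 1) because recomputed spreads can differ across
   conventions on small cells. Cells with fewer than two sites fall back to
   the all-biome pooled spread with a warning, so subsets stay processable.
2. **Reduction factor** `RF`: a catalogued accuracy multiplier in (0, 1] per
   accepted field method — seven aboveground, eight belowground, four total
   — smaller for more direct, complete methods. When several methods
   underlie one above- or belowground estimate, their mean rounded to one
   decimal is reported; exact midpoints round toward the RF of the dominant
   component (fine roots for belowground estimates, the largest-flux
   component aboveground), and toward the smaller RF when dominance is
   unknown.
3. **Series length** `l` (years): a multiyear mean is less uncertain, so the
   per-measurement uncertainty is `S = P · RF / √l`.

Per site, measurement campaigns (grouped by measurement years within a
scope) aggregate as root-sum-square over `N` — `S_site = √(ΣS²)/N`, the
identity for one measurement and `S/√N` for `N` equal ones — and the above-
and belowground parts combine Euclidean to the total:
`S_TNPP = √(S_ANPP² + S_BNPP²)`. Methods that only resolve total NPP (eddy
covariance, radiocarbon, peat accumulation, process models) bypass the
propagation: their `S` is drawn directly from the TNPP spread. No
per-component error propagation finer than the ANPP/BNPP split is attempted,
as that would require splitting the reduction factors beyond what the method
catalogue supports. A site lacking any belowground measurement has no
propagated total uncertainty — the estimate is reported missing rather than
guessed. The whole chain is scale-equivariant: rescaling every NPP value
rescales every `S` by the same factor.

## Climate and management classification

The **Köppen–Geiger main class** is computed from monthly normals in the
modern formulation: polar when the warmest month stays below 10 °C;
otherwise arid when annual precipitation is below ten times the dryness
threshold (2·MAT, +28 if ≥ 70 % of precipitation falls in the high-sun
half-year, +14 if neither half dominates); then tropical (coldest month
≥ 18 °C), temperate (coldest month above 0 °C) or cold. The 0 °C
temperate/cold boundary is the modern choice; the older −3 °C variant is
available via an argument. The high-sun half-year is April–September in the
northern hemisphere, October–March in the southern; equatorial sites use the
April–September convention.

The **aridity index** is annual precipitation over annual potential
evapotranspiration, undefined at zero PET (an explicit error, never a
silent `Inf`). The five classes partition `[0, ∞)`: hyper-arid `[0, 0.03)`,
arid `[0.03, 0.2)`, semi-arid `[0.2, 0.5)`, dry sub-humid `[0.5, 0.65]`,
humid `> 0.65`. The published class definitions use strict inequalities
that leave the boundary points unassigned; a convention had to be pinned,
and these half-open intervals are it.

**Biome rules** follow production shares: above the treeline is tundra;
grain/tuber cropping is cropland (always managed); woody-dominated (> 50 %)
outside arid climates is forest; herb-dominated below the treeline is
grassland; cold-climate shrub/herb co-dominance (each < 50 %) is peatland;
dry, patchy-cover systems are dry shrubland. The cold shrub-herb systems
overlap on paper, so precedence is pinned: treeline first, then cold-climate
peatland, then arid/patchy shrubland, with transition zones resolved by the
larger production share. Because stored biome labels encode expert judgment
the rules only approximate, the classifier doubles as a validator
(rule output against stored label) rather than a replacement. Management
rules encode the per-biome intervention windows (thinning/harvest within
50 yr or fertilization within 25 yr makes a forest managed; plantations
count as natural after 10 untouched years; annual burning and low-moderate
grazing leave grasslands unmanaged; fertilization experiments make any
tundra/peatland/shrubland managed). Missing antecedents default to
unmanaged with a low-confidence flag rather than failing.

## Quality control

Three advisory checks, none of which mutates data: coordinate bounds (plus
an off-land test when the user supplies a gridded land mask — none is
bundled); summation consistency, recomputing every complete level and
flagging absolute differences from the stored aggregates above a tolerance
(default 1 g m⁻² yr⁻¹, absorbing source-table rounding); and stratified
boxplot outliers, flagging site-level ANPP/BNPP outside
`[Q1 − k·IQR, Q3 + k·IQR]` within biome or climate-region strata. The
whisker multiplier `k = 1.5` is the standard boxplot convention, exposed as
an argument since nothing deeper fixes it; strata with fewer than five
sites are skipped with a warning. Quartiles use the same percentile
convention as the uncertainty module.

## Uncertainty-weighted Miami regression

The Miami model predicts NPP as the minimum of a temperature-limited
logistic branch and a precipitation-limited saturating branch:

$$\mathrm{NPP} = \min\!\left(\frac{A}{1 + e^{\,b - cT}},\;
A\left(1 - e^{-dP}\right)\right)$$

with the classic coefficients `A = 3000` g m⁻² yr⁻¹, `b = 1.315`,
`c = 0.119` °C⁻¹, `d = 0.000664` mm⁻¹ as defaults and starting values. The
fit minimizes `Σ wᵢ (NPPᵢ − f(Tᵢ, Pᵢ))²` with `wᵢ = 1/Sᵢ²` (weighted) or 1
(unweighted). The `min()` makes the objective non-smooth, so optimization is
derivative-free Nelder–Mead from eight jittered starts (positive parameters
on the log scale, fixed jitter seed, best converged start kept); with
clean data the generating parameters are recovered to machine precision,
and with all-equal `S` the weighted objective is a constant multiple of the
unweighted one, so both fits return identical parameters. Sites with
`S = 0` are floored at the smallest positive `S` with a message. Fits
expose `tidy()`, `glance()`, `predict()` and `autoplot()`.

`compare_fits()` reports the relative difference in mean predicted NPP,
`(mean_unweighted − mean_weighted)/mean_unweighted`, over a common
evaluation set. One subtlety matters when interpreting it: with symmetric,
mean-zero heteroscedastic noise, weighting improves parameter *precision*
(lower RMSE across replicates) but does not shift mean predictions in a
fixed direction. A systematically lower weighted prediction arises when the
noisy methods are also *biased* — which is precisely the premise of
method-specific reduction factors: inaccurate methods err in both direction
and magnitude. The package's simulations therefore test the precision gain
under mean-zero noise, and the direction of the contrast under
biased-and-noisy high-NPP sites, separately.

## The synthetic generator

`generate_database()` exists so every pipeline stage is testable without
downloads. Its defaults are the study conditions the package targets: 456
sites in biome proportions 206/145/34/34/21/16
(forest/grassland/cropland/peatland/tundra/dry shrubland) and climate
proportions 191/125/80/45/14 (cold/temperate/tropical/arid/polar,
normalized); series lengths 42 % single-year, 50 % in 2–5 yr, the rest
6–16 yr; ~11 % of sites with only a total-NPP record; one third of sites
managed (croplands always). Each site draws a climate region compatible
with its biome, monthly normals built to satisfy that region's Köppen
criteria (sinusoidal temperature around a region-specific mean, seasonal
precipitation, a linear temperature proxy for PET), true NPP from the Miami
surface, and component records split by biome-specific shares with
scope-matched methods from the catalogue. Observed values add Gaussian
noise with spread proportional to the method's RF over `√l` (a 20 %
base coefficient of variation at RF = 1, `noise_model` scales it; 0 is
noise-free). Components a biome lacks are explicitly flagged absent so
default sites gate complete; a configurable fraction of sites instead omit
one main component, unflagged, to exercise incomplete gating. One global
seed drives named RNG sub-streams per table, so adding a table never
perturbs existing draws, and generation is bit-reproducible.

What the generator does *not* emulate: real geographic clustering (longitude
is uniform), correlated soil/climate covariates, reporting idiosyncrasies
(mixed campaigns, inconsistent stored aggregates, typos), within-site
interannual variability, or skewed method error. Green tests on synthetic
data therefore demonstrate the pipeline's algebra, gating and determinism —
not that real deposits are clean. Two consequences are worth noting
explicitly. First, generated normals classify back to their intended
Köppen region essentially always (the tests require ≥ 95 %), which real
1-km climatologies will not match. Second, even noise-free databases can
show boxplot "outliers": with the published biome-by-climate mixes, arid
croplands and polar peatlands sit far below their biome medians on the
Miami surface itself, so the zero-noise tests assert that any flagged value
equals its true NPP rather than that the flag set is empty — on real data
most flagged extremes are genuine, which is why the QC is advisory.

## Problem sizes and numerical conventions

The shipped tests run the generator at 25–456 sites, the percentile and
Köppen oracles at 1,000 random cases each, and the weighted-regression
replicate experiment at 50 replicates of 120–200 sites — sizes chosen so
the statistical assertions (binomial tolerances on marginals, RMSE
orderings) are stable at fixed seeds. Ties in RF averaging are the only
deliberate midpoint rule in the package; everywhere else standard R
floating-point semantics apply, and equality assertions on recomputed
quantities use tolerances at or below 10⁻¹⁰. Degenerate inputs fail loudly:
empty measurement sets, zero PET, series lengths below one year, carbon
fractions outside (0, 1] and mixed-scope RF averaging are all errors, not
warnings.

## Known limitations

* The column mapping layer adapts table and column names only; it does not
  translate component vocabularies or unit systems beyond the carbon/dry
  mass conversion.
* Biome spreads recomputed from a small or filtered database differ from
  spreads computed on a full deposit; the `p_table` argument to
  `database_uncertainty()` exists to supply externally tabulated spreads
  for exact replication.
* The mixed-campaign provenance flag records the caveat but no uncertainty
  inflation is applied for year-mismatched above/belowground pairs.
* Fertility (L/M/H) is stored and validated but never inferred; Excel
  deposits must be exported to CSV or SQLite first; no gap-filling of
  missing minor components is provided.
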