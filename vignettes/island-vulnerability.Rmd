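---
title: "Assessing island vulnerability to climate change: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing island vulnerability to climate change: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(islevuln)
```

## The problem

Island endemic faunas face climate change with nowhere to go: their entire
range is one island or a handful of islands in one archipelago. Assessing
which islands are most at risk requires more than projecting climate —
exposure alone says nothing about whether the resident species can tolerate
or adjust to the change. `islevuln` implements a full island-scale
vulnerability assessment in the standard three-component framework:

* **Exposure** — how much the local climate will change;
* **Sensitivity** — how intrinsically fragile the resident endemics are;
* **Adaptive capacity** — how much room the system has to absorb or escape
  the change.

The three components are standardized, aggregated, and combined into a
single vulnerability score per island with the TOPSIS multicriteria method.
Everything runs on synthetic archipelagos with plantable structure, so the
whole pipeline is testable offline; the on-disk interfaces (CSV tables,
multi-tree Newick) accept pre-extracted real data in the same layout.

## Exposure: local climate change as a standardized distance

For each climate grid point of an island, exposure is the standardized
Euclidean distance (SED) between the current and future climate:

$$\mathrm{SED} = \sum_{k=1}^{6} \frac{(b_k - a_k)^2}{s_k^2},$$

where $a_k$ and $b_k$ are the current and future values of climate variable
$k$ and $s_k$ is a seasonality standardizer — temperature seasonality for
the three temperature variables (annual mean temperature, maximum
temperature of the warmest month, minimum temperature of the coldest
month), precipitation seasonality for the three precipitation variables
(annual, wettest-month and driest-month precipitation). The value is the
printed sum of squared terms, with no square root: a monotone transform
would not change island ranks but would change the standardized values, so
the formula is kept as published in the climate-novelty literature.
Per-point SEDs are averaged per island; with several future scenario blocks
(e.g. different GCMs) the per-block island means are averaged
arithmetically. Whether to average across GCMs or build an ensemble climate
first is genuinely open; the per-block-then-average rule was chosen because
it keeps every block inspectable (`multi_scenario_exposure()` returns both).

Buffered variants (100 km, 500 km) include the grid points of neighbouring
islands within planar distance of the island's own point set — the
projection-free analogue of "a species may find suitable climate nearby".
The headline pipeline uses buffer 0; the buffers are optional outputs, since
the per-island statistic is the conventional report.

Non-positive standardizers would make SED unbounded, so they are an error
by default; an explicit `seasonality_floor` can be configured to substitute
a floor with a warning instead.

## Sensitivity: four trait variables

Per species: habitat breadth and diet breadth (counts of distinct
categories — low breadth means high specialization), generation length in
years, and ecological redundancy. Redundancy is the size of the species'
*functional entity*: the group of species sharing an identical combination
of main diet, foraging niche, foraging period, habitat niche breadth, and a
body-mass category. A species counts itself, so a functionally unique
species has redundancy 1 — "the number of species sharing the combination"
is read self-inclusively, which keeps the minimum at 1 rather than 0.

Body mass is continuous and must be categorized to form entities. No
canonical scheme exists, so the package bins $\log_{10}$ mass into
quantile bins (default 4) over the **global** species pool: quantiles
cannot produce empty bins under the strongly right-skewed mass
distributions typical of mammals. Both the bin count and the pooling scope
are exposed (`mass_bins`; entities are computed once globally, then
averaged per island over occupants).

Island sensitivity is the arithmetic mean of each variable over the
island's occupying species; multi-island endemics contribute to every
island they occupy. The values are emitted raw — all direction flips happen
in one place, in scoring, so the orientation of every variable is auditable
in a single table (`default_variable_spec()`).

## Adaptive capacity: four island variables

* **Surrounding land mass** — the sum of the proportions of land within
  nested buffers (100, 1000, 10,000 km) around the island, in [0, 3]. High
  values mean low geographic isolation and hence nearby refuges. The score
  is kept in this native orientation and enters the component positively;
  this avoids a double negation that would otherwise haunt every downstream
  sign.
* **Protected-area fraction** of island area, in [0, 1], taken as an input.
* **Phylogenetic distinctiveness** — the fair proportion (FP) index: each
  edge's length divided equally among its descendant tips and summed along
  each root-to-tip path. FP is computed on every tree of an ensemble, with
  polytomies resolved uniformly at random (inserted edges of length 0, so
  the total branch length — and therefore the FP total — is conserved), and
  averaged per species across trees, then per island across occupants. The
  desk-scale default ensemble is 100 trees; FP ensemble means stabilize
  well before that, and the size is configurable up to the thousands used
  with posterior tree sets.
* **Extinction rate** — past vertebrate extinctions divided by total
  vertebrate richness. Counter-intuitively this enters adaptive capacity
  **positively**, following the extinction-filter hypothesis: where
  extinction pressure has already been high, the surviving pool is enriched
  in resistant species. The orientation is declared (not hidden) in
  `default_variable_spec()` precisely because it is the one sign a reviewer
  should want to see.

Whether per-island FP should be a mean or another summary is not settled
convention; the mean is used, consistent with how the other three
components aggregate.

## Standardization, orientation, aggregation

Three 0–1 standardizations are supported, all rank-preserving and all
mapping the observed minimum to 0 and maximum to 1:

* `minmax` — linear rescale $(x - x_{\min})/(x_{\max} - x_{\min})$;
* `log_minmax` — $\ln(x+1)$ first (compressing the influential upper
  tail), then min–max; negative inputs are shifted by the minimum first,
  with a warning;
* `cdf` — percentile ranks (average ties), rescaled to [0, 1].

A constant variable is uninformative; it standardizes to 0.5 everywhere
with a warning, a value symmetric under direction flips so it cannot bias
either end of a component.

Standardized variables are oriented (`increases_component` is the
identity; `decreases_component` reflects as $1-x$), summed within each
component, and the three component sums are re-standardized with the same
scheme so each component lives on [0, 1].

## TOPSIS vulnerability

With islands as alternatives and the three components as criteria, the
positive ideal solution (no vulnerability) takes the observed minimum
exposure, minimum sensitivity and maximum adaptive capacity; the negative
ideal is the reverse. Vulnerability is the relative distance

$$V_i = \frac{d^+_i}{d^+_i + d^-_i},$$

with Euclidean distances to the two ideals, so an island at the positive
ideal scores 0 and one at the negative ideal scores 1 — this is $1$ minus
the classical TOPSIS closeness coefficient, the unique relative-distance
form with those endpoints. Adaptive capacity enters as a benefit criterion
rather than being pre-inverted; the ideal-solution definitions encode its
direction, mirroring how the framework is stated. Criterion weights are
equal by default (no weighting is part of the method's definition here) and
exposed as a config vector; the final score is **not** re-standardized, so
reported ranges (e.g. 0.14–0.83 on the default synthetic scenario) are
meaningful rather than forcibly stretched to [0, 1]. If all islands
coincide on all components, every score is defined as 0.5, with a warning.

## Robustness analyses

* `correlation_screen()` — pairwise Spearman correlations within each
  component, flagging $|\rho| \ge 0.7$ (the conventional collinearity
  threshold). On independently drawn variables at $n = 100$ islands the
  screen flags nothing in the overwhelming majority of seeded replicates —
  a calibration check of the threshold itself.
* `leave_one_out()` — every variable whose component retains at least one
  other variable is dropped in turn; component scores and vulnerability are
  recomputed and compared to the full model by Spearman's rho. Exposure's
  single variable cannot be dropped and is skipped with a notice.
* `archipelago_summary()` — archipelago mean, sample ($n-1$) standard
  deviation (0 for singletons, reported rather than NA so plots never lose
  bars), descending-mean rank, and the fraction of islands above the 0.5
  high-vulnerability threshold.
* `association_report()` — Spearman's rho with two-sided p-values for
  vulnerability against island-mean traits, components, and endemic
  richness. P-values are asymptotic by default (`exact = TRUE` switches to
  the exact null distribution, sensible below $n \approx 10$ without
  ties). Trait associations are computed at island level over island-mean
  traits; a pooled species-level variant would conflate within- and
  between-island variation.

No multiple-testing correction is applied: the reports are descriptive
companions to a single composite indicator, not a family of confirmatory
tests.

## The synthetic-data generator

`vuln_scenario()` fixes the study conditions; its defaults are the
conditions under which the package's guarantees are exercised:

* 5 archipelagos × 8 islands; 12+ endemics per island (every island passes
  the strict ">5 species" inclusion filter by construction; the filter is
  still applied, never bypassed); about 30% multi-island endemics, confined
  to their archipelago — endemism semantics would otherwise break the
  archipelago roll-ups.
* ≥ 10 climate grid points per island on abstract planar coordinates (km).
  No map projection and no spatial autocorrelation within islands: the
  real spatial structure of island climates is not documented well enough
  to emulate honestly, so the generator does not pretend to.
* Per-archipelago warming offsets evenly spaced 0.5–2.5 °C (scaled
  per-variable, drying precipitation profile), five GCM-like blocks with
  multipliers 1 ± 0.15, Gaussian noise per variable.
* Traits: log-normal generation length (median 4 y) and body mass (median
  150 g), 1–6 habitats, 1–5 diets, four levels per categorical redundancy
  trait — plausible magnitudes for insular small mammals; none of these
  distributions is prescribed by convention, so they are config, not code.
* 100 trees per ensemble, 20% of internal edges collapsed to polytomies,
  branch lengths uniform on (0.1, 1) so retained edges are strictly
  positive.
* One master seed, split hierarchically per stage (islands → climate →
  species → trees → per-tree resolutions), so changing a downstream stage's
  configuration never perturbs upstream draws and every run is exactly
  reproducible.

A scenario can *plant* one maximally vulnerable archipelago (maximal
warming, fully specialized species with tripled generation length, zero
protected area, zero surrounding land, zero past extinctions). Planted
structure is the generator's ground truth: the pipeline should rank that
archipelago first, and the test suite demands it does so in ≥ 95 of 100
seeded replicates.

What passing on synthetic data does **not** show: performance on real
rasters and range polygons (GIS extraction is out of scope; the pipeline
starts from tables), realistic climate autocorrelation, or realistic trait
covariance (traits are drawn independently). The tests establish that the
arithmetic, orientations, and rankings are right — not that any particular
real-world archipelago is the most vulnerable.

## Numerical choices and degenerate inputs

* SED with a non-positive standardizer: error by default, optional floor.
* Constant columns: standardize to 0.5 with a warning; Spearman's rho
  against a constant is NA with a warning, never silently 0.
* TOPSIS with all-identical islands: all scores 0.5, with a warning.
* Rank ties: average ties everywhere (`rank(..., "average")`), except
  archipelago ranks, which must be a permutation of 1..n and therefore use
  first-occurrence tie-breaking.
* Quantile mass bins with duplicated breaks (heavily tied masses) collapse
  to the distinct breaks; a fully degenerate mass vector yields one bin.
* Oracle-level equivalences (vectorized SED vs per-point loops, FP totals
  vs branch-length sums) are tested at 1e-12 relative / 1e-9 absolute.

## Problem sizes in the test suite

The suite exercises FP conservation on 100 random trees of 10–200 tips,
SED equivalence on 20 islands × 50 points, TOPSIS monotonicity on 1000
random perturbation trials, standardization contracts on 1000 random
vectors, planted-structure recovery on 100 replicates of the 5 × 8 default
(20-tree ensembles — FP means are already stable there), and rank
congruence across standardizations on a 100-island scenario. These sizes
were chosen as the smallest at which the properties are meaningfully
exercised with comfortable margins.

## Known limitations

* Planar geometry throughout; no great-circle distances, no projections.
* Habitat categories are opaque labels; no habitat-classification parsing.
* The PCA biplot of variable structure is deliberately not part of the
  tested core (it is routine ordination with no acceptance surface).
* Sea-level rise and extreme events are outside the framework's scope.
* The TOPSIS distance is Euclidean and unweighted by default; alternative
  MCDA methods are out of scope.
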