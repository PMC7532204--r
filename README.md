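# islevuln

Climate-change vulnerability assessment for island endemic faunas.

Island endemics cannot track a shifting climate the way continental species
can: their whole range is one island, or a few islands of one archipelago.
`islevuln` implements the standard three-component vulnerability framework
at island scale and rolls it up to archipelagos, for conservation
scientists who want a reproducible, testable version of the analysis
rather than a one-off script.

## The method

Vulnerability is a function of three components, each built from
standardized, direction-oriented variables:

- **Exposure** — local climate change per grid point as the standardized
  Euclidean distance between current and future climate,
  `SED = Σₖ (bₖ − aₖ)² / sₖ²` over six bioclimatic variables (three
  temperature, standardized by temperature seasonality; three
  precipitation, standardized by precipitation seasonality), averaged per
  island and across future scenario blocks (GCMs). Optional 100/500 km
  buffered variants include neighbouring islands' grid points.
- **Sensitivity** — island means of four species traits: habitat breadth,
  diet breadth, generation length, and ecological redundancy (the size of
  each species' functional entity — the group sharing an identical
  combination of categorized traits: main diet, foraging niche, foraging
  period, habitat niche breadth, body-mass bin).
- **Adaptive capacity** — surrounding land mass within nested buffers,
  protected-area fraction, fair-proportion evolutionary distinctiveness
  averaged over a tree ensemble with randomly resolved polytomies, and the
  past extinction rate (entering positively, per the extinction-filter
  hypothesis).

Variables are standardized to [0, 1] by one of three schemes (min–max,
ln(x+1) min–max, or CDF percentile ranks), oriented, summed per component
and re-standardized. **TOPSIS** then scores each island by its relative
distance to the positive ideal (minimum exposure and sensitivity, maximum
adaptive capacity) and the negative ideal (the reverse):
`V = d⁺ / (d⁺ + d⁻)`, 0 = least, 1 = most vulnerable.

Robustness tools reproduce the analyses that should accompany any
composite indicator: a within-component correlation screen (|rho| ≥ 0.7),
leave-one-variable-out congruence, archipelago means ± s.d. with ranks,
and Spearman associations of vulnerability with traits, components and
richness.

A seeded synthetic-archipelago generator (islands, climate grids, traits,
occurrences, phylogeny ensembles) makes the whole pipeline runnable and
testable with no downloads, and can *plant* a maximally vulnerable
archipelago as ground truth. Real pre-extracted data are accepted in the
same CSV/Newick layout.

## Worked example

```r
library(islevuln)

sc <- vuln_scenario(seed = 2026, planted_archipelago = "A5")
b  <- run_pipeline(list(scenario = sc, method = "minmax"))

head(b$vulnerability, 3)
#>   island_id d_pos d_neg vulnerability
#> 1     A1_I1 0.331  1.50         0.181
#> 2     A1_I2 0.802  1.30         0.382
#> 3     A1_I3 0.552  1.39         0.284

b$archipelagos
#>   archipelago_id mean_vulnerability    sd rank n_islands frac_high
#> 1             A5               0.89 0.040    1         8         1
#> 2             A1               0.27 0.083    2         8         0
#> 3             A3               0.27 0.079    3         8         0
#> 4             A2               0.25 0.074    4         8         0
#> 5             A4               0.21 0.053    5         8         0
```

Island vulnerability spans 0.13–0.92 here. The planted archipelago A5 —
maximal warming, fully specialized long-generation species, no protected
areas, no surrounding land, no extinction filter — is recovered at rank 1
with every one of its islands above the 0.5 high-vulnerability threshold
(`frac_high = 1`), while the four unplanted archipelagos sit at 0.21–0.27.
The association report on the same run gives rho = 0.34 (p = 0.03) for
island-mean generation length, rho = −0.97 for adaptive capacity, and no
richness association (rho = −0.07, p = 0.67) — vulnerability is not a
richness artefact.

Each stage is also callable on its own (`generate_*`, `sed_point`,
`island_exposure`, `assign_entities`, `fair_proportion`, `fp_ensemble`,
`standardize`, `topsis`, `leave_one_out`, ...); `run_pipeline()` accepts a
YAML config or an in-memory list and, given `out_dir`, writes every stage
table as CSV plus a manifest, byte-identically across re-runs of the same
config.

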