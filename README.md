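# leaftaper

Morphometrics of single-vein (conifer) leaves from the half-width profile:
how leaf width tapers along the midrib, and where the leaf is widest.

Single-vein leaves are bilaterally symmetric about the midrib, so a leaf's
shape reduces to its *half-width profile* — half-width `Y` (cm) against
position `X` (cm) along the midrib, measured from the base. `leaftaper`
fits the quadratic taper model

    Y = C + B1·X + B2·X²

to such profiles, derives the vertex (position of maximum width)

    X0 = −B1 / (2·B2)        (requires B2 < 0)

and the **tipping leaf length ratio** `X0 / Xmax` — the fraction of total
leaf length at which the leaf is widest (2/5 for an ideal ovate leaf, 1/3
oblong, 1/2 elliptic). Because the ratio captures the split between a
leaf's basal and distal parts, it is a compact descriptor for comparing
cohorts (e.g. stand ages) of fast-growing conifers such as Chinese fir.

The package covers the whole path from image to statistics:

* **Extraction** — `binarize()`, `find_axis()`, `measure_profile()`: from a
  scanned leaf mask (PNG/TIFF, default 600 dpi) to a width profile sampled
  every 0.1 cm perpendicular to the base-tip axis.
* **Model** — `fit_taper()`, `taper_vertex()`, `tipping_ratio()`,
  `batch_fit()`, `pooled_fit()`: per-leaf OLS fits with validity flags,
  plus pooled group-level curves.
* **Statistics** — `cohort_summary()`, `anova_lsd()`, `log10_ratio()`,
  `normality_check()`: descriptive trait tables and one-way ANOVA with
  unprotected Fisher LSD pairwise tests and compact letter displays.
* **Synthetic ground truth** — `leaf_shape_spec()`, `generate_profile()`,
  `generate_cohort()`, `render_mask()`: quadratic, ovate, oblong and
  elliptic leaves with known parameters, rendered to binary masks for
  round-trip validation.
* **Pipeline** — `run_pipeline()`, `demo_config()`, `report_tables()` and
  the `exec/leaftaper` command-line front end: simulate → extract → fit →
  summarize → report, deterministic under a single seed.

## Worked example

Simulate one leaf that follows the 30-yr-old stand's published taper
curve with 0.01 cm measurement noise, fit it, then push it through the
full image round trip:

```r
library(leaftaper)

p <- generate_profile(leaf_shape_spec("quadratic", length_cm = 4,
       coefficients = c(0.120, 0.040, -0.014), noise_sd_cm = 0.01, seed = 7))
fit_taper(p)
#> <taper_fit> synthetic: Y = 0.1214 + 0.0443 X + -0.0153 X^2 (R2 = 0.882)
#>   vertex X0 = 1.4469 cm, Xmax = 4.0000 cm, tipping ratio = 0.3617

mask <- render_mask(p, dpi = 600)      # 88 x 951 px binary mask
fit_taper(measure_profile(binarize(mask)))
#> <taper_fit> synthetic: Y = 0.1208 + 0.0447 X + -0.0154 X^2 (R2 = 0.878)
#>   vertex X0 = 1.4541 cm, Xmax = 4.0005 cm, tipping ratio = 0.3635
```

The fitted curve recovers the generating coefficients (C = 0.120,
B1 = 0.040, B2 = −0.014; vertex 1.4286 cm, ratio 0.357) to within the
noise, and re-extracting the rendered mask moves the estimates by less
than a pixel's worth.

The demo pipeline runs six cohorts of 18 leaves built from the six
published age-group models:

```r
rep <- run_pipeline(demo_config(seed = 1), output_dir = "demo_out")
rep
#> <leaf_run_report> 108 leaves, 108 fits (54 valid)
#>   group n_leaves n_valid n_B2_nonnegative n_vertex_out_of_range ...
#> 1     2       18      18                0                     0
#> 2     5       18       0                0                    18
#> 3    10       18       0                0                    18
#> 4    13       18       0                0                    18
#> 5    23       18      18                0                     0
#> 6    30       18      18                0                     0

rep$anova$length_cm
#> <anova_lsd> F(5, 102) = 4.1639, p = 0.00175 (alpha = 0.05)
#>   group  n     mean letters
#> 1    13 18 4.827380       a
#> 2    23 18 4.455056      ab
#> 3     2 18 4.229749      bc
#> 4    10 18 3.948917      bc
#> 5    30 18 3.890577       c
#> 6     5 18 3.760434       c
```

Groups sharing no letter differ at p < 0.05 under Fisher LSD. The QC
table is doing real work here: the 5-, 10- and 13-yr published group
curves have B1 ≤ 0, so their pooled vertex lies at or below the leaf base
— those fits are flagged `vertex_out_of_range` and excluded from ratio
summaries rather than contributing meaningless ratios. The pooled 30-yr
model reproduces the closed-form vertex −B1/(2·B2) = 0.040/0.028 =
1.4286 cm exactly (`rep$group_models`).

`report_tables()` (or the `output_dir` argument above) writes
deterministic CSVs: per-leaf fits, trait summaries with SD/SE/CV%/CI,
pooled group models, ANOVA letters, QC counts and per-group densities.

From a shell, the same pipeline is:

```sh
exec/leaftaper run-all --config inst/extdata/demo-config.json --out demo_out
```

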