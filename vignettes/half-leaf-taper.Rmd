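---
title: "Half-leaf width taper models: methods and design choices"
author: "leaftaper"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Half-leaf width taper models: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leaftaper)
```

## The model

Single-vein (conifer) leaves are bilaterally symmetric about the midrib, so
their shape is fully described by the *half-width profile*: half-width
$Y$ (cm) as a function of position $X$ (cm) along the midrib, measured from
the base. The package models this profile as a quadratic taper curve

$$Y = C + B_1 X + B_2 X^2,$$

where $C$ is the half-width at the base, $B_1$ the initial broadening rate
and $B_2$ (cm$^{-1}$) the curvature. For $B_2 < 0$ the curve attains its
maximum at the vertex

$$X_0 = -\frac{B_1}{2 B_2},$$

and dividing by the total leaf length $X_{max}$ gives the **tipping leaf
length ratio** $X_0 / X_{max}$: the fraction of the leaf's length at which
it is widest, i.e. the relative size of its basal part. Taxonomic ideals
anchor the scale — an ovate leaf is widest at $2/5$ of its length, an
oblong leaf at $1/3$, an elliptic leaf at $1/2$. The ratio summarizes the
trade-off between the basal part (radial transport capacity) and the distal
part (axial path length), which is what makes it a useful cohort-level
descriptor across, for example, stand ages.

Model assumptions worth keeping in mind:

* **Bilateral symmetry.** Widths are measured as full perpendicular extents
  and halved; any real asymmetry about the midrib is averaged away.
* **A straight midrib.** The axis is a straight line; curved or twisted
  leaves are out of scope (see Limitations).
* **A single quadratic arc.** Leaves with shoulders, lobes or multiple
  width maxima will fit poorly (low $R^2$) and can place the vertex outside
  the blade; such fits are flagged, not silently used.

## The estimation pipeline

### Width-profile extraction from masks

`binarize()` turns a grayscale scan into a single-leaf mask: Otsu threshold
(leaf darker than the scanner background) unless a threshold is supplied,
largest connected component kept (secondary components above 10% of it
trigger a warning), interior holes filled, minimum area 50 px. Binary input
is taken at face value (nonzero = foreground), so the operation is
idempotent on masks.

`find_axis()` estimates the midrib. For any silhouette symmetric about its
midrib, the midrib *is* the major principal axis of the foreground pixels,
so the axis direction is taken from the first principal component and the
endpoints from the extreme projections onto it. This is deliberately not
the literal longest boundary chord: leaves with a blunt (truncated) base
have their longest chord running from the tip to a *corner* of the base,
which tilts the axis and starves the first measurement station. The
principal axis coincides with the longest chord for ideal symmetric leaves
and is robust to boundary shape at the ends.

Base and tip are disambiguated by comparing the average foreground width in
the two terminal 10% windows: the blade of a single-vein leaf broadens just
above the petiole while the apex tapers to an acute point, so the **wider
terminal window marks the base**. When the windows differ by less than 5%
(a circle, a symmetric ellipse) the choice is flagged ambiguous; for a
symmetric leaf the ratio is 1/2 either way.

`measure_profile()` lays stations every `interval_cm` (default 0.1 cm,
also accepting 0.2 cm or any positive value) from the base, and measures at
each station the perpendicular extent of foreground within a one-pixel band
— stations at the extreme tip with no foreground are kept as width 0.
Conversions use one convention throughout: pixel size is $2.54/\mathrm{dpi}$
cm, pixel centers are the continuous coordinates, and a run of $n$ pixel
centers spans $n$ pixels of material (hence the "+1 px" in lengths). With
these conventions a rendered leaf re-extracts with half-widths within one
pixel and length within 0.5%.

### Fitting

`fit_taper()` is ordinary least squares of $Y$ on $(X, X^2)$ with
intercept — unweighted, because every station is an equally informative
width measurement. Standard errors come from the classical covariance
estimator; adjusted $R^2$ uses $p = 2$ predictors,
$1 - (1 - R^2)(n-1)/(n-3)$. Design choices:

* **Trailing zero stations are kept** by default — a zero width at the tip
  is a real observation of blade closure. `drop_trailing_zeros = TRUE` is
  available for profiles whose tail zeros are artifacts.
* **$X_{max}$ is the measured total leaf length**, not the last station
  position (they differ by less than one interval).
* **Validity.** A fit is `valid` only when $B_2 < 0$ and
  $0 < X_0 < X_{max}$. Everything else is retained with a reason
  (`B2_nonnegative`, `vertex_out_of_range`, `too_few_points`) and excluded
  from ratio summaries; the pipeline's QC table counts the reasons per
  group. Fewer than 5 stations or fewer than 3 distinct positions is a
  flagged fit, never an error.
* **Numerical guard.** A fitted $|B_2|$ below
  $10^{-10}\max|Y| / X_{max}^2$ (a constant or linear profile, where the
  true curvature is zero up to floating-point noise) is treated as 0 —
  otherwise a $\sim 10^{-17}$ curvature would place a meaningless "vertex"
  somewhere on the axis. A zero-residual fit reports zero standard errors.

`pooled_fit()` stacks all stations of a group and fits one quadratic — a
pooled regression, clearly labelled as such, since group-level curves could
equally be built by averaging per-leaf coefficients; its $X_{max}$ is the
group's mean leaf length. Pooled models answer "what does the average
blade of this cohort look like"; per-leaf fits feed the ratio statistics.

### Cohort statistics

`cohort_summary()` produces the descriptive row used throughout: n, mean,
SD ($n-1$), SE $= \mathrm{SD}/\sqrt{n}$, CV% $= 100\,\mathrm{SD}/$mean,
median, min, max, and a **t-based** confidence interval for the mean
(default 95%) — with the small per-group n typical of this kind of study
(n = 18), normal intervals would be visibly too narrow.

`anova_lsd()` is a classical one-way ANOVA followed by **unprotected**
Fisher LSD pairwise t-tests: every pair is tested with the pooled MSE and
its error degrees of freedom regardless of the omnibus outcome, matching
the common statistical-software meaning of "LSD test". The compact letter
display uses the insert-and-absorb algorithm on the pairwise significance
matrix with groups in descending-mean order, which guarantees that groups
sharing no letter differ at level $\alpha$ and every non-significant pair
shares a letter.

The tipping ratio is **log10-transformed** (`log10_ratio()`) before the
group comparison — the raw ratio is bounded and right-skewed — while
descriptive summaries stay on the raw scale. Because published tables of
this kind display raw-scale means with letters, and it is usually ambiguous
which scale produced the letters, the pipeline reports the ANOVA on *both*
scales (`tipping_ratio_log10` and `tipping_ratio_raw`) and defaults to the
log10 version.

`normality_check()` wraps the Shapiro–Wilk test for the per-trait
normality screen.

## The synthetic generator

The generator exists so that every stage can be validated against known
ground truth. What it emulates, and how:

* **Quadratic family** — leaves that follow the taper model exactly, with
  coefficients of the user's choice (e.g. the published group models in
  `cunninghamia_taper_models()`); negative analytic values truncate to 0
  (the blade has closed). The ground-truth ratio $-B_1/(2B_2)/L$ is stored
  with each profile, including values outside $(0,1)$ when the
  coefficients place the vertex outside the blade.
* **Ideal families** — `ovate`, `oblong`, `elliptic`, with ground-truth
  ratios 0.4, 1/3, 0.5 by construction. The elliptic family is a true
  half-ellipse. The ovate and oblong families are **parabolic arcs** with
  the apex at the peak fraction and zero half-width at the tip (giving a
  blunt base and an acute apex). This choice is deliberate: egg-like curves
  built from beta functions or joined half-ellipses have quadratic-fit
  vertices at 0.45–0.48 when their true peak is at 0.40 — a quadratic
  cannot follow their skew — so they cannot serve as ground truth for a
  pipeline whose estimator *is* the quadratic fit. The parabolic arc is the
  idealization consistent with the model, and its theoretical ratio is
  recovered exactly by a noise-free fit and within ±0.02 through the full
  image round trip.
* **Measurement noise** — additive iid Gaussian on half-width, truncated
  at 0, default SD 0. Real width measurement error is roughly
  pixel-scale; 0.01 cm (about 2.4 px at 600 dpi) is the level used in the
  recovery tests.
* **Cohorts** — leaf lengths drawn from a truncated Normal (positive, and
  optionally capped at `length_max_cm`); per-leaf sub-seeds are derived
  deterministically from the cohort's master seed, so one integer
  reproduces the whole cohort. The demo configuration caps each group's
  lengths at its quadratic's positive root (`demo_config()`): a leaf longer
  than its model's blade-closure point cannot follow that model, and
  without the cap the occasional too-long leaf perturbs the pooled
  coefficients away from their exact published values.
* **Rasterization** — `render_mask()` draws, at each pixel column,
  $2\times$ half-width pixels symmetric about a horizontal midrib, with
  half-widths converted to pixels by round-half-up (stated because the
  one-pixel round-trip tolerance depends on the rounding rule). Default
  600 dpi, the resolution at which conifer leaf shape is comfortably
  resolved (a typical half-width of 0.165 cm is then ~39 px).

What the generator does **not** emulate: midrib curvature, margin
serration, petiole remnants, scanner artifacts (shadows, dust, uneven
illumination) or asymmetry about the midrib. Passing the synthetic round
trips therefore demonstrates that the geometry, unit conversions and
estimators are correct — not that the pipeline is robust to every artifact
of real scans. Real-scan use should inspect the QC table and the per-leaf
$R^2$ distribution.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `interval_cm` | 0.1 | station spacing along the midrib (cm) |
| `dpi` | 600 | raster resolution; pixel = 2.54/dpi cm |
| `min_area` | 50 px | smallest acceptable foreground |
| `alpha` | 0.05 | pairwise LSD significance level |
| `confidence` | 0.95 | level of the t-interval on means |
| `transform` | log10 | ratio scale for the ANOVA |
| `noise_sd_cm` | 0 | generator measurement noise (cm) |
| `max_half_width_cm` | 0.165 | apex half-width of ideal families (cm) |

## Problem sizes used by the test suite

The suite validates at the scale of the motivating study: 6 cohorts × 18
leaves (108 fits) for recovery and pipeline checks, 100 leaves × 41
stations for noisy ratio recovery, 1000 random profiles for the OLS/normal-
equations equivalence, and 2000 replicates of a 6 × 18 null for ANOVA
calibration. These sizes give stable Monte-Carlo margins while keeping a
full run in tens of seconds.

```{r demo, eval = FALSE}
rep <- run_pipeline(demo_config(seed = 1))
rep$group_models   # pooled per-group taper curves; 30-yr vertex at 1.4286 cm
rep$qc             # three groups have no in-blade vertex (B1 <= 0)
```

A known property of the published group-level models deserves emphasis:
three of the six (the 5-, 10- and 13-yr groups) have $B_1 \le 0$, so their
*pooled* vertex lies at or below the leaf base and no in-blade tipping
ratio exists for the pooled curve, even though per-leaf ratios are all
positive. The pipeline neither hides nor "fixes" this: those fits carry
`vertex_out_of_range`, are counted in QC, and are excluded from ratio
summaries. It is a useful reminder that pooled-curve vertices and means of
per-leaf ratios are different quantities.

## Numerical and degenerate-input choices

* Positions start at 0 at the base (the first station sits on the base
  edge); the intercept $C$ is sensitive to this convention, which is why it
  is fixed package-wide rather than configurable.
* Station width = perpendicular extent (max − min + 1 px) of foreground in
  a one-pixel band, robust to single-pixel boundary noise; an empty band is
  width 0.
* Ties in the base/tip endpoint (flat base edge) resolve to the pixel
  nearest the midline; eigenvector sign and group order are canonicalized
  so identical inputs give byte-identical outputs.
* All-identical ANOVA inputs return $F = 0$, $p = 1$, shared letters;
  perfect separation returns $F = \infty$, $p = 0$.
* An empty ratio set after validity filtering produces an $n = 0$ summary
  row, headers-only report files and a warning — never an error.

## Limitations

* The straight-axis assumption makes strongly curved leaves out of scope;
  a curved-skeleton axis would be the natural extension.
* The quadratic is a two-parameter shape family: leaves that are
  near-linear in their distal half can fit with $|B_2|$ so small that the
  vertex is numerically fragile — visible as ratio errors an order of
  magnitude larger than for well-curved leaves at the same noise level.
  The validity flags catch the extreme cases ($X_0$ outside the blade) but
  a small-$|B_2|$ valid fit still deserves a look at its standard errors.
* No vulnerability/hydraulic interpretation is computed here; the package
  stops at the morphometric quantities.
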