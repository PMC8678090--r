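---
title: "Canopy nitrogen models and the high-NUE screen: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Canopy nitrogen models and the high-NUE screen: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canopynue)
```

# The problem

Nitrogen-use efficiency (NUE) in rice shows up not as a single trait value
but as the *shape* of a variety's canopy nitrogen trajectory across growth
stages: a high-NUE line holds moderately high nitrogen through vegetative
development, carries the collection's highest nitrogen into full heading
(FHS) and milk ripening (MRS), and loses it slowly after booting.
`canopynue` estimates those trajectories non-destructively from multispectral
plot imagery and screens collections for that dynamic signature.

# The measurement chain

## Empirical-line calibration

The camera reports digital numbers (DN). With six ground panels of known,
spectrally flat reflectance (0.03, 0.12, 0.24, 0.36, 0.56, 0.80), the
per-band linear sensor model

$$\rho_\lambda = \mathrm{DN}_\lambda \cdot \mathrm{Gain}_\lambda + \mathrm{Offset}_\lambda$$

is fitted by ordinary least squares of panel reflectance on mean panel DN
(`fit_empirical_line()`), independently per band with no cross-band
smoothing. Ordinary (unweighted) least squares is used; panel statistics use
the arithmetic mean of interior pixels. Calibrated output is not clipped by
default — out-of-range reflectance is a diagnostic, not an error — with an
opt-in clip to $[0, 1.2]$. Degenerate inputs fail loudly: fewer than two
panels, or identical DN across panels in any band.

## Vegetation indices

Plot reflectance is the arithmetic mean over the plot rectangle's interior
pixels (all rectangles are 0-based, half-open, row-major — one convention
shared by every module). Indices are computed from mean reflectance
(*index-of-means*), not averaged per-pixel indices; the two differ on
non-uniform plots, and index-of-means is the convention that matches a single
reported index per plot. Band lookup is by exact nominal center (800 nm,
720 nm, ...) with no nearest-band fallback, so a missing band is an error
naming the band rather than a silent substitution.

## Nitrogen models

Tillering-stage (TS) records are excluded before fitting
(`exclude_tillering()`): early in the season the canopy does not cover the
paddy water, whose low reflectance in every band inflates NDRE.

*Model I* is the quadratic $N\% = a\,x^2 + b\,x + c$ in $x =$ NDRE, fitted by
least squares (`fit_model_i()`, requiring $n \ge 4$ and at least three
distinct $x$).

*Model II* is the exponential $N\% \times LAI = \alpha e^{\beta x}$, fitted
by nonlinear least squares **on the original scale** (`fit_model_ii()`), so
the error structure is additive in the response, matching how such fits are
displayed on untransformed axes. The log-linear OLS of $\log y$ on $x$ is
used only to initialize; when some $y \le 0$ the initializer falls back to
user-supplied starting values. Non-convergence after 200 Levenberg–Marquardt
iterations is an error carrying the iteration diagnostics.

Both fits report a pseudo-$R^2 = 1 - SS_{res}/SS_{tot}$ (about the mean),
the adjusted version $1 - (1 - R^2)(n-1)/(n-k-1)$ with $k$ the number of
predictors (2 for the quadratic, 1 for the exponential), the Pearson
correlation of observed vs fitted, and a two-sided F-type p-value. Both
plain and adjusted $R^2$ are reported because published fit statistics are
often ambiguous between the two. A constant response is handled as the
defined limit: zero slope/curvature coefficients, intercept at the mean, and
$R^2 = 0$. No multiple-testing correction is applied anywhere; all p-values
are two-sided.

The maturity split (`split_by_gd()`) uses a 100-day growth duration cutoff
(transplanting to maturation) separating middle-season from early/late-season
rice; the boundary itself is assigned to the late group (GD ≥ 100 → LM),
a choice the cutoff's verbal definition leaves open.

# The phenotype screen

`build_stage_series()` ranks varieties within each stage (rank 1 = highest;
ties share the minimum rank). `classify_high_nue()` turns the qualitative
phenotype into three clauses, each with an exposed threshold
(`phenotype_rule()`):

| clause | default | meaning |
|---|---|---|
| reproductive rank | ≤ 1 at FHS **and** MRS | the collection's highest reproductive-stage nitrogen |
| vegetative band | each of TS, JS, PIS, BS in the 40–95th percentile | moderate-high, but not the extreme top, before heading |
| decline | $(v_{BS} - v_{MRS})/2$ ≤ collection median | slow post-booting nitrogen loss |

These numeric thresholds are this package's operationalization of a
phenotype that is described verbally in the field; they are deliberately
config-exposed rather than hard-coded. Percentiles use the empirical CDF
over complete varieties (so the top variety at a stage sits at the 100th
percentile and fails a 95 cap); the decline threshold uses the type-7
sample quantile with ≤, which makes the rule monotone: relaxing any
threshold can only add flags. The decline rate uses the BS→MRS endpoints
rather than a fitted slope — with only six stages a two-point rate is robust
and directly expresses "still high at FHS/MRS". Varieties with missing
stages are excluded with a warning, never silently passed or failed. The
classifier accepts any nitrogen measure (chemical `n_eqa`, Model-I `n_uav`,
Model-II `n_lai_uav`) and records which was used.

Field traits follow the standard formulas: SSR = 100·full/total (%),
GNP = full/EPN, TGW = 5 × 200-grain weight (g), GYP = full-grain weight per
plant (g), GY = GYP · plants/area · 10 (kg/ha — the factor 10 reconciles the
10,000 m²/ha scale-up with the g→kg conversion), NUE = GY / N applied
(kg grain per kg N), undefined at the 0 kg/ha treatment (reported `NA`, not
0 or infinity). The 13.5% standard moisture deduction is an opt-in flag
because it belongs to the combine-harvest yield convention only. Group
comparisons use Student's pooled t by default — matching the label such
tables usually carry — with Welch behind a flag since group variances are
rarely equal in practice.

# The synthetic field generator

`synth_config()` fixes the study conditions; every generator is a pure
function of (config, seed) and is bitwise reproducible.

**Trajectories.** Non-high-NUE varieties cycle through three baseline
templates (N% by stage ≈ {3.2, 3.0, 2.8, 2.5, 1.8, 1.2} and a lusher/sparser
variant) plus Gaussian jitter (sd 0.2 % N), floored just above the
quadratic model's intercept so every value stays invertible. Planted
high-NUE varieties are built *against the realized collection*: vegetative
values at the 70th percentile of the others, FHS/MRS at the others' maximum
plus a 0.15 % N margin, and the post-booting decline capped below the
others' median. This constructive approach makes the planted-label /
classifier-recovery property exact at zero measurement noise, which is what
lets the test suite treat the classifier as a round trip.

**Reflectance.** The true N% is mapped through the inverse of the quadratic
model (larger root; admissible N% in $[c, a+b+c)$, i.e. NDRE in $[0,1)$ —
the branch on which NDRE is positive and increasing in nitrogen). The 800 nm
band is anchored at 0.45, the 720 nm band set to reproduce the NDRE, and the
other ten bands follow a smooth green-canopy spectral shape tied to those
anchors. At tillering the plot signal is the convex mixture
$f \cdot \rho_{water} + (1-f) \cdot \rho_{canopy}$ with $f = 0.4$ by
default and a water spectrum that is near-zero in the NIR — which is what
makes the TS points deviate systematically from the Model-I curve and
motivates their exclusion.

**LAI.** By default LAI is derived as
$\alpha e^{\beta x} / N\%$ at the true NDRE, so the same synthetic field is
exactly consistent with *both* nitrogen models at zero noise and the
end-to-end pipeline recovers both sets of generating coefficients. The cost
is realism: the implied LAI (~1.1–1.7) is low for mid-season rice and its
seasonal shape is inherited from the nitrogen curve. A jittered template
mode (`lai_mode = "template"`, peaking at booting) is available when LAI
realism matters more than joint model consistency.

**Sensor and scene.** DN = (ρ − offset)/gain per band (defaults gain 0.005,
offset 0.01) plus i.i.d. Gaussian pixel noise — no spatial correlation, the
simplest model that exercises aggregation. DN is floating point by default;
a `quantize` flag rounds to the 10-bit range [0, 1023]. Panel sizes, plot
sizes and within-plot pixel noise are not constrained by any published
value; the defaults (6 px panels and plots, 0.5 DN noise) are arbitrary and
flagged as such in the config.

**Ground instruments.** `n_eqa` = true N% + N(0, 0.05) — the chemical
reference is precise; SPAD = 12·N% + 8 + N(0, 1), an affine surrogate;
`n_npen` = max(N% + noise, 2.0), reproducing the N-pen meter's saturation:
readings cluster at the 2% floor exactly where the instrument fails to
separate low-nitrogen material. The dosage trial parameterizes group means
on the agronomic scale (GYP 38.5 vs 20.6 g at 0 kg N/ha, the high-NUE line
ahead at every treatment) and derives grain counts and the 200-grain weight
so configured means reproduce exactly at zero noise.

**What the generator does not emulate** — and hence what green tests do
*not* establish about real data: radiative-transfer canopy optics
(BRDF, illumination geometry, shadows), spatially correlated sensor noise,
mosaicking/registration artifacts, mixed pixels at plot edges, genotype ×
environment interaction, and any real spectral diversity among varieties
beyond the nitrogen signal. Passing the recovery tests shows the *pipeline*
is self-consistent and unbiased under its own assumptions, not that the
printed model coefficients would re-emerge from a new field trial.

# Numerical choices and test scale

OLS fits go through `stats::lm`, the exponential fit through
`minpack.lm::nlsLM`; the test suite checks both against independent
closed-form normal-equation oracles rather than trusting any one solver.
Coefficient-recovery assertions use 1e-6; zero-noise sensor round trips
1e-9 to 1e-10. Model JSON stores coefficients both as numbers and as
`%.17g` decimal strings so a write/read round trip is bit-exact; CSV tables
round-trip below 1e-12; rasters are 32-bit TIFF with a JSON sidecar
(wavelengths, value kind, scale, seed, config hash). Every artifact embeds
the seed and an 8-hex-digit config hash, making a run reproducible from its
outputs alone.

Stochastic checks run at the design scale of the two collections — 51 and
42 varieties × 6 stages (306 and 252 records; 255 after tillering
exclusion) — with 200 replicate seeds for fit-statistic recovery and 100
seeds for classifier recovery, sizes at which the whole suite completes in
seconds while keeping Monte-Carlo error well inside the ±0.05 acceptance
bands used in the tests.

# Limitations

- The phenotype thresholds (top rank, 40–95th percentile band, median
  decline) are one reasonable quantification of a verbal phenotype; real
  screens should sweep them (`phenotype_rule()`) rather than trust defaults.
- Model coefficients are trial-specific; the quadratic/exponential *forms*
  travel, the numbers do not.
- The empirical-line model assumes a linear sensor and stable illumination
  between panels and plots; no atmospheric or BRDF correction is attempted.
- Rasters are pixel-coordinate only: no CRS, georeferencing or mosaicking.
- NUE here is grain yield per kg N supplied; uptake and utilization
  components are not separated.
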