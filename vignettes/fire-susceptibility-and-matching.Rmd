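---
title: "Frequency-ratio fire susceptibility and matching-based protection effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency-ratio fire susceptibility and matching-based protection effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(firescape)
```

# The analysis in one page

`firescape` implements a two-part observational analysis of vegetation fire
on an equal-area grid (1-km cells by default).

**Part 1 — susceptibility.** Each causative factor (tree cover, land cover,
elevation, slope, aspect, fire-season temperature, population density,
travel time to cities, distance to roads, distance to forest edge) is
divided into class intervals. For class $i$ of a factor, the frequency
ratio is

$$\mathrm{FR}_i = \frac{n_{\text{fire},i}/N_{\text{fire}}}{n_i/N},$$

the fire share of the class over the cell share of the class, computed over
valid cells of a stratum (protected, non-protected, or all). The per-cell
Fire Susceptibility Index is the sum over factors of the FR of the class
the cell falls in, $\mathrm{FSI} = \sum \mathrm{FR}$. Cells at or above a
quantile of FSI within a stratum are the "highly susceptible" pixels;
factors are ranked there by the mean of their per-cell FR values,
descending — higher mean FR, more dominant causative factor.

**Part 2 — protection effect.** Each valid grid cell is a unit with binary
treatment $T$ (protected), binary outcome $Y$ (fire presence) and the
nine-covariate vector $X$ (land cover, being categorical, is excluded from
matching). The estimand is the average treatment effect on the treated,
$\tau = E[Y_1 - Y_0 \mid T=1]$. Every treated unit is matched to the
control(s) minimizing the Mahalanobis distance
$\sqrt{(x_t-x_c)^\top S^{-1}(x_t-x_c)}$, $S$ the pooled all-units sample
covariance, with replacement and a per-covariate caliper of 1 sample
standard deviation. A diagnostic logistic propensity model
$p(X)=\Pr(T=1\mid X)$ and a Pearson correlation screen at $|r| \ge 0.95$
accompany the matching; the identification assumptions are the usual ones
of matching estimators (unconfoundedness given $X$, overlap), which the
data cannot verify.

# Key conventions and numerical choices

* **Grid.** Abstract equal-area plane; geometries must be exactly equal to
  align. No geodesy: real rasters are co-registered upstream. Rasters are
  exchanged as plain-text ESRI ASCII grids.
* **Classing.** Continuous intervals are left-closed/right-open, the last
  interval closed, so a value exactly at an interior breakpoint belongs to
  the upper class. Values outside the breakpoints become nodata and are
  counted. Default breakpoints mirror the class intervals of the study
  system (tree cover 25–50/51–75/75–100 %, elevation
  0–100/100–500/500–2000/>2000 m, 5° slope bins, eight aspect octants,
  10 °C temperature bins, population 0–25/25–50/50–75/75–150/150–300/>300
  km⁻², distance bins 0–1/1–5/5–50/>50 km) and are fully overridable.
* **FR formula.** The prose definition of the frequency ratio is ambiguous
  between several ratios; the package fixes the standard form
  (fire share)/(cell share), which satisfies the algebraic identity
  $\sum_i \mathrm{FR}_i\, n_i/N = 1$ (tested to 1e-12) and reproduces the
  >1/<1 interpretation rule.
* **Degenerate FR inputs.** A stratum with no fire cells is an error naming
  the stratum; a class with cells but no fires has FR 0; empty classes are
  omitted. A class observed in a cell but missing from the FR table is a
  consistency error rather than a silent NA.
* **Stratified FSI.** The susceptibility map is stratified by default: a
  protected cell is scored with the protected-stratum FR table and vice
  versa (matching the separate per-stratum supplementary tables of the
  study design); pooled scoring is available by passing the `all`-stratum
  table to `fire_susceptibility_index()` directly.
* **Selection quantile.** "Highly susceptible" is not quantified in the
  source design; the default is the 0.90 FSI quantile within the stratum,
  and the ranking aggregates per-cell FR by the arithmetic mean (also a
  choice the source leaves open).
* **Terrain.** Horn's eight-neighbour gradient with edge replication;
  slope $=\arctan\lVert\nabla z\rVert$; aspect is the compass bearing of
  steepest descent, clockwise from north, with flat cells given the
  sentinel −1 and excluded from classing (they fall outside the aspect
  breaks). The sentinel does enter the matching covariates as a value;
  with smooth synthetic terrain flat cells are essentially absent.
* **Resampling.** Majority filter for categorical layers (nodata excluded
  from the vote, ties broken by the lowest category code — deterministic
  and order-independent); Keys cubic convolution with $a=-0.5$ and edge
  clamping for continuous layers (exact on constant and linear fields,
  tested to 1e-9); equal-split proportional allocation for count layers
  (exactly conservative). Euclidean distance layers use the exact two-pass
  squared distance transform.
* **Fire ingestion.** Detections with confidence ≥ 95 (inclusive) are
  kept; fire is presence/absence per cell, cumulative over the record (a
  per-year split is possible upstream but not modelled). Malformed rows
  are rejected per-row and counted, never fatally.
* **Matching numerics.** $S$ is Cholesky-factored; matching distances are
  computed in the whitened space, then recomputed for the selected
  candidates via the difference form so exact covariate twins report
  distance 0. Ties within a relative tolerance of 1e-8 are all retained
  with equal weights. If $S$ is numerically singular a ridge of
  $10^{-8}\,\mathrm{tr}(S)/d$ is added and recorded. The caliper is
  per-covariate in SD units (the convention of the matching software
  family the design follows); a treated unit whose tied-best matches all
  violate it is excluded and counted. Only matching with replacement is
  implemented.
* **Variance.** The Abadie–Imbens estimator: the variance of matched
  differences around the ATT plus the control-reuse correction
  $\sum_c (K_c^2 - Q_c)\hat\sigma_c^2$, with $K_c$ the control's total
  match weight, $Q_c$ its summed squared weights (so fractional tie
  weights keep the correction nonnegative), and $\hat\sigma_c^2$ from the
  nearest same-group neighbour, $(Y_c - Y_{\ell(c)})^2/2$.
* **Balance.** Before-matching columns use all treated vs all controls;
  after-matching control moments are weighted by total match weight with
  frequency-weight normalization ($\sum K - 1$ denominator), which makes
  an exact-twin design reproduce the treated moments and variance ratios
  of exactly 1. Zero control variance yields an `Inf` ratio with a
  warning.
* **Propensity model.** IRLS to tolerance 1e-10 or 100 iterations;
  separation is flagged when any fitted score is within 1e-8 of 0 or 1 and
  scores are clipped to $[10^{-6}, 1-10^{-6}]$. The model is diagnostic:
  matching is on the covariates, not the score.

# The synthetic landscape

The generator states a world with the statistical structure the analysis
assumes, with every parameter fixed up front:

* Spatially autocorrelated fields are FFT-smoothed Gaussian white noise
  (autocorrelation length 8 cells by default) — chosen because the only
  assumption carried over from real data is "spatially structured".
* Elevation spans 0–2500 m; temperature is 28 °C at sea level minus the
  standard environmental lapse rate 0.0065 °C/m, plus 0.5 °C noise, so
  elevation and temperature are strongly anticorrelated (exactly −1 at
  zero noise), emulating the strong negative correlation seen in real
  covariate stacks while staying below the 0.95 collinearity screen.
* Population density is log-normal (median 30 km⁻²) and decreases with
  elevation; tree cover is smooth in [25, 100] % (the forest range of the
  study system); land cover is a 5-class thresholded latent field; roads
  are 5 random transects and cities 5 random cells, feeding the distance
  and travel-time layers (30 km/h conversion). The forest mask behind the
  distance-to-edge layer uses a 60 % tree-cover threshold — an internal
  construction constant, since with all cells above 25 % a "forest
  boundary" needs a higher cut to exist.
* Protection is assigned at the level of 25 candidate disk patches (radius
  4–10 cells): a patch is accepted with probability
  $\mathrm{logit}^{-1}(1\cdot z_{\text{elev}} - 1\cdot z_{\text{pop}})$ of
  its mean standardized elevation and log-population, so protected cells
  are biased toward remote, high, sparsely populated terrain — the
  confounding the matching must remove. Setting both coefficients to 0
  gives the unconfounded null world.
* Fire is Bernoulli per cell with logit
  $\beta_0 + \beta^\top z + \delta T$ on standardized covariates, defaults
  $\beta_0=-1.5$, $\beta$ = (elevation −0.5, temperature +0.4, population
  +0.5, tree cover −0.3, distance to road −0.3, travel time −0.2, distance
  to edge −0.2, slope 0, aspect 0) per SD, and protection effect
  $\delta=-0.5$ — a baseline fire rate around 0.2 and a true ATT near
  −0.05, the order of magnitude of protection effects reported for real
  tropical fire regimes.

The truth record (true ATT over treated cells, expected stratum rates) is
a deterministic closed-form function of the emitted stack and config, so
estimator tests compare against counterfactual truth rather than against a
noisy replicate. When caliper exclusions shrink the matched treated set,
recovery tests compare the estimate with the truth recomputed over the
matched treated units — that is the estimand a caliper estimator targets.

What the generator does **not** emulate: satellite georegistration and
swath geometry, multi-sensor detection characteristics, temporal fire
dynamics, spatial correlation of fire *given* the covariates, and land
cover influencing fire beyond its correlation with the latent fields. A
green test therefore establishes correctness of the estimators under the
stated world, not robustness to, e.g., spatially autocorrelated outcome
noise — on real data, cellwise matching at 1 km ignores dependence between
neighbouring cells, and reported standard errors inherit that limitation.

# Known limitations

* Matching in nine continuous dimensions retains finite-sample bias of
  order $n^{-1/9}$; no bias correction is applied because the mirrored
  design uses none. The recovery tests bound the practical consequence at
  the default problem size (mean bias within Monte-Carlo error of zero,
  nominal CI coverage ≥ 80 % over seeds).
* The caliper rule tests the tied-best match set only; a treated unit is
  excluded rather than falling back to the next-nearest in-caliper
  control. This follows the documented contract and keeps the estimator's
  matched set interpretable.
* Travel time in file mode is consumed as a ready covariate; no network
  routing is performed.
* Protected-area boundaries enter as a raster mask; polygon handling is
  out of scope.
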