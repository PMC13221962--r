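---
title: "Modeling organoid growth under chemo- and radiotherapy"
author: "pdtogrowth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling organoid growth under chemo- and radiotherapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdtogrowth)
```

## The models

`pdtogrowth` models the post-treatment growth of patient-derived tumor
organoids (PDTOs) measured by brightfield imaging. The measured quantity is
the organoid diameter $D$ (µm); the modeled quantity is the cell number
$N = (D/D_0)^3$, with $D_0 = 22.5$ µm the average diameter of a pancreatic
tumor cell. Untreated organoids follow logistic growth,

$$\frac{dN}{dt} = \lambda N \left(1 - \frac{N}{K}\right),$$

with intrinsic growth rate $\lambda$ (day⁻¹) and carrying capacity $K$
(cells), conveniently reported as the carrying diameter
$D_K = D_0 K^{1/3}$.

Treatment acts through time-varying per-capita killing rates that multiply
the same saturating growth term (a Norton–Simon-type assumption: kill is
proportional to the unperturbed growth rate). A single drug dose produces
one Gaussian kill pulse,

$$C(t) = a\, e^{-b (t - T_c)^2},$$

where $a$ is drug sensitivity (day⁻¹), $b$ the inverse-squared width of the
killing window (day⁻²) and $T_c$ the day of peak effect. Irradiation
produces two waves with *fixed* unit widths (1 day²),

$$R(t) = u_1 e^{-(t - T_1)^2} + u_2 e^{-(t - T_2)^2},$$

an early wave near day 4 and a stronger secondary wave near day 8. The wave
widths are part of the model definition and are never fitted; the ordering
$T_1 < T_2$ is enforced at the type level, and a fit that converges with
swapped waves is relabeled before reporting.

Radiation also splits the population at $t = 0$ into active (surviving) and
inactive (lethally damaged) compartments via the linear-quadratic survival
fraction $A_0 = N_0 e^{-\alpha d - \beta d^2}$, $I_0 = N_0 - A_0$, with dose
$d$ in Gy. Inactive cells do not proliferate and are cleared at rate $\mu$;
both compartments occupy the shared carrying capacity. The chemo pulse in
the combined (chemoradiation) model acts on active cells only. Model
reductions are exact: setting $a = 0$, or $u_1 = u_2 = d = 0$, collapses
each treated model onto its nested submodel, and the test suite verifies
the full reduction lattice to 1e-8 relative.

Fixed constants, overridable through the configuration
(`default_study_config()`): $\mu = 0.3$/day, $\alpha = 0.015$/Gy,
$\beta = \alpha/9.5$/Gy², $D_0 = 22.5$ µm.

## Numerical choices

The four right-hand sides are compiled C code integrated with `deSolve`.
The default integrator is `lsoda` at `rtol = 1e-8`, `atol = 1e-10` (cell
units), with an explicit Runge–Kutta pair (`ode45`) available through the
`method` argument; both are verified against the closed-form logistic
solution (and, for the chemo model, against its erf-based closed form) to
better than 1e-6 relative, and the two-compartment models against an
independent R-coded integration at 1e-11 tolerance. These systems are
non-stiff at realistic parameter scales; `lsoda` was chosen because the
calibration layer is integration-bound and it is ~2.5× faster at equal
accuracy. Round-off excursions of the state below zero are clipped at zero
up to 1e-8 cells; anything larger aborts as an integration error.

## Calibration protocol

Fitting minimizes the sum of squared errors **in cell-number space**
(the NMSE, $\sum_i (X_i - Y_i)^2 / \sum_i X_i^2$, is a scale-free
*reporting* statistic, not the loss). The initial population $N_0$ is fixed
to the day-0 measurement and never fitted, which both mirrors the
experimental design and removes a scale degeneracy. Each fit runs bounded
Levenberg–Marquardt least squares (`minpack.lm`) from Latin-hypercube
start points spread over the parameter box — 10 by default, raised to 25
for the five-parameter radiotherapy and fixed-C schemes where 10 starts
occasionally land in a local minimum with one wave pinned at its bound —
and the best final SSE wins, with
near-ties (below 1e-10 relative) broken toward the smaller parameter norm.
The multi-start seed is explicit (default 20260303) so entire report
bundles are bit-reproducible.

The group-specific schemes follow the study protocol:

| scheme | free | fixed | bounds |
|---|---|---|---|
| control | $\lambda, D_K$ | $N_0$ | $\lambda \in [0,3]$, $D_K \in [30, 1200]$ µm |
| chemo | $a, b, T_c$ | $\lambda, K$ from control means | $a \in [0,5]$, $b \in (0,2]$, $T_c \in [0,14]$ |
| radiotherapy | $\lambda, u_1, u_2, T_1, T_2$ | $K$, $\mu$, $\alpha$, $\beta$, $d$ | $u \in [0,10]$, $T \in [0,14]$ |
| CRT, fixed-R | $a, b, T_c$ | radio pulse from the matching RT arm; $\lambda, K$ | as chemo |
| CRT, fixed-C | $\lambda, u_1, u_2, T_1, T_2$ | chemo pulse from the chemo arm; $K$ | as radiotherapy |

The control fit is internally parameterized in $(\lambda, D_K)$ rather than
$(\lambda, K)$; the cubic map makes the search box isotropic and
well-conditioned. Line-level fixed values are the across-organoid means of
the control fits, with $K$ taken from the mean carrying diameter.

**Identifiability flagging.** A parameter that the optimizer drives onto
its *upper* search bound has no interior optimum: that trajectory does not
identify it. This happens routinely for $D_K$ when a noisy 5-point
trajectory is still far from saturation — in a noise-only simulation about
a third of control fits run away to the bound, and including them would
inflate the population mean of $D_K$ by >60%. `population_summary()`
therefore excludes bound-flagged values *per parameter* (the same fit's
identified parameters are retained; natural zero lower bounds, where the
truth may legitimately sit, are not flagged). Population summaries report
the across-organoid mean, its 95% CI half-width
$t_{0.975,\,n-1}\, s/\sqrt{n}$, and the median; across-line differences use
one-way ANOVA for means and Kruskal–Wallis for medians, the conventional
pair when the generating tests are unstated.

The largest size achievable within a sample is estimated as the upper limit
of a wide confidence interval of the mean carrying diameter,
$\bar{D}_K + t_{1-(1-\ell)/2,\,n-1}\, \mathrm{se}$ with $\ell = 0.999$
(`achievable_size_bound()`); with the reported group sizes (33/30/30) this
reproduces the published 578.8/700.3/695.8 µm maxima to the printed
precision.

Model comparison uses the Gaussian-likelihood information criteria
$\mathrm{AIC} = m\ln(\mathrm{SSE}/m) + 2k$ and
$\mathrm{BIC} = m\ln(\mathrm{SSE}/m) + k\ln m$; they are reported only when
$m \ge k+1$ and degenerate to $-\infty$ sentinels on perfect fits.

## The synthetic-study generator

No raw measurements are deposited with the study, so validation rests on
synthetic studies whose generating truths are the published group-level
estimates. `default_study_spec()` emulates the design: 3 patient lines
(#7800, #8510, #11777) × 6 arms (control; FOLFIRINOX chemo; RT at 4 and
8 Gy; CRT at 4 and 8 Gy), 20–40 organoids per group (the #7800 counts
33/20/30/30/21/26 are the published ones; other groups use 30), measurement
days 0, 2, 4, 6, 7 (plus 8, 9 for RT arms), and a daily-grid option
mirroring the study's supplementary daily-imaging experiment.

Choices the data do not dictate, made once:

* **Initial size**: diameters drawn from N(100, 15²) µm truncated at 40 µm
  — organoids were treated while small (< 200 µm), and 100 µm is an 88-cell
  initial state.
* **Heterogeneity**: each kinetic parameter is drawn independently from a
  normal truncated at its admissible bound ($\lambda, a, b, u \ge 10^{-4}$;
  peak times $\ge 0$; $K > N_0$, $T_1 < T_2$ by redraw), with the
  between-organoid SD set to the published 95% CI half-width. The
  CI-*implied* across-organoid SD ($\mathrm{hw}\sqrt{n}/t$) is dominated by
  per-organoid estimation error — for #7800 it would be ~438 µm on $D_K$
  and put ~30% of organoids above the study's own largest-achievable-size
  estimate — whereas the half-width keeps that ceiling near the 96th
  percentile for every line. No correlation structure is imposed (the
  reported association between growth rate and sensitivity is a documented
  extension, not modeled).
* **Measurement noise**: multiplicative lognormal on diameter,
  $D_{obs} = D_{model}\, e^{\varepsilon}$,
  $\varepsilon \sim N(0, 0.05^2)$ per time point (day 0 included, which is
  why $N_0$ anchoring matters): diameters are positive and image-derived
  size error scales with size. Note 5% diameter noise is ~15% cell-number
  noise through the cubic map.

Everything is deterministic given the master seed, the caller's RNG stream
is restored, and the sampled truths travel with the dataset (attribute
`truth`) so recovery can be scored.

What the generator does **not** emulate: segmentation artifacts, organoid
fusion, dropout/censoring, parameter correlations, and any dose–response
structure beyond the printed per-dose parameter sets. Passing recovery
tests therefore validate the calibration machinery under the model's own
assumptions, not the model against real biology.

## Validation design and known limitations

*Noise-free recovery.* Every calibration scheme, refitted on noise-free
trajectories generated at the published parameter sets, recovers the
generating values within 1% (2% for the five-parameter radiotherapy
scheme). This is the package's primary acceptance surface
(`scripts/acceptance.R` recomputes it from scratch).

*Noisy replicate studies.* 50 replicate studies of 30 organoids drawn
under the generator's default conditions (between-organoid heterogeneity
at the published spreads, 5% diameter noise): the across-organoid 95% CI
of the population mean is checked for coverage of the generating
population value. $\lambda$, $D_K$ and $T_c$ cover in well over 90% of
replicates. The chemo kill strength $a$ does **not** reach 90% coverage
(and the correlated window parameter $b$ sits marginally below it):
unweighted least squares in
cell space on 5-point declining trajectories under multiplicative noise
carries an intrinsic $O(\sigma^2)$ upward bias of ~9% in $a$, comparable
to the CI half-width. An independent estimator (closed-form erf solution
of the chemo model + `L-BFGS-B`) reproduces the same bias, so it is a
property of the estimation protocol itself, inherited by design; fixing
group-mean growth parameters additionally leaks growth heterogeneity into
the kill estimates. Users comparing drug sensitivities across groups
should rely on the comparison being bias-shared, not bias-free.

*Scheme-contrast study.* The chemoradiation decomposition (fit C(t) with
R(t) fixed vs the reverse) is compared on data generated *under the
fixed-R scheme* — growth at the control means, radiation fixed at the
line's RT-arm estimates, chemo pulse heterogeneous around the CRT-arm
estimates — on the daily grid, noise-free. Under those conditions the
matched fixed-R refit beats the mismatched fixed-C refit for ≥ 95% of
organoids, reproducing the study's misfit asymmetry qualitatively. Two
findings motivated this design: on the sparse 5-day grid the fixed-C
scheme has five free parameters against four informative points and can
interpolate *any* trajectory, so no contrast can exist there; and with 5%
noise the structural misfit is smaller than the noise floor. The printed
misfit magnitudes are not reproducible from synthetic data — the real
trajectories are not realizations of the fitted model family.

*Treatment response.* $\mathrm{TR} = \ln(N_{untreated} / N_{treated})$,
with the untreated counterfactual given by the logistic model at the
line's control parameters started from the organoid's own day-0 size. The
verbal definition of the ratio would make effective therapy negative; the
published values are positive with "larger = more effective", forcing
this orientation. Whether "size" meant diameter or cell count (and the log
base) is not stated — cell count and natural log are used here, so TR
validation is restricted to orderings (chemo > RT at day 7, RT day 9 >
day 7, CRT ≥ chemo at day 7), which hold on synthetic data at the
published parameter sets.

Problem sizes used by the test suite (50×30 noisy fits per scheme, 60
organoids in the contrast study, 100-draw property loops) were chosen so
the whole suite exercises every scheme end to end in a few minutes on one
CPU.

## A worked example

```{r example, eval = FALSE}
set.seed(1)
spec <- default_study_spec()
ds <- generate_study(spec["7800.control"], seed = 42)
fits <- lapply(ds$trajectories, fit_control)
population_summary(fits, c("lam", "DK"))
```

The full protocol — control → chemo → RT → CRT in dependency order, with
parameter tables, NMSE tables, the TR table, killing curves, forecasts and
a seed-stamped manifest — is `run_study()`; `exec/pdto` wraps it for the
shell (`simulate`, `fit`, `report`, `forecast`).
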