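---
title: "Methods: gradient-based multiple-stressor analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gradient-based multiple-stressor analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the statistical machinery in `stressorcurves`: the
models, their assumptions, the tunable parameters, and the numerical and
design choices made where more than one defensible option existed.

## 1. From optical density to growth rate

Each well of a plate experiment yields a biomass time series: OD600
readings on a schedule of every 2 h for the first 12 h and then every 4 h
until carrying capacity. `fit_gompertz()` reduces a series to a maximum
specific growth rate by nonlinear least squares on the log fold change
$y(t) = \ln(\mathrm{OD}(t)/\mathrm{OD}(0))$ with the modified Gompertz
curve

$$y(t) = A\,\exp\!\left(-\exp\!\left(\frac{\mu_{max} e}{A}(\lambda - t) + 1\right)\right),$$

parameterized directly in the quantities of interest: $\mu_{max}$ (h⁻¹,
the slope at the inflection), lag $\lambda$ (h) and asymptote $A$ (natural
log units of fold change). This is the standard microbiological form in
which $\mu_{max}$ *is* the reported growth rate. Two details matter:

* **Anchoring.** The observed fold change is measured relative to the
  first reading, so the model is evaluated as
  $y(t;\theta) - y(t_1;\theta)$. This makes fitting the exact inverse of
  the package's own simulator and removes a small systematic offset (the
  Gompertz curve is not exactly zero at $t=0$).
* **Multi-start.** The optimizer (bounded Levenberg–Marquardt) is run from
  a 3 × 3 grid: $\lambda$ at 0 %, 25 % and 50 % of the time span crossed
  with $\mu_{max}$ at 0.5×, 1× and 2× the steepest finite-difference slope
  of $y$; $A$ starts at $\max(y)$. The best fit by RSS is kept. Bounds are
  $\mu_{max}\ge 0$, $0\le\lambda\le\max(t)$, $A>0$.

Wells whose maximum log fold change stays below the **no-growth
threshold** (default 0.05 log units, configurable) are declared
non-growing with $\mu_{max}=0$ instead of being fitted: a flat series
carries no information about $\lambda$ or $A$, and unconstrained fits on
such data are unstable. Wells where every start fails are flagged
non-converged and excluded from downstream fits with a logged count.
Uncertainty in $\mu_{max}$ is *not* propagated further — the downstream
mixed model treats each well's rate as a datum, the common convention in
performance-curve work.

## 2. Performance-curve model

Growth rate $r$ along a gradient $x$ (temperature in °C, pH in pH units,
salinity in g NaCl/L) is described phenomenologically by a quadratic
mixed-effects model

$$r_{xi} = (\beta_0 + \varepsilon_{0i}) + (\beta_1 + \varepsilon_{1i})x +
(\beta_2 + \varepsilon_{2i})x^2,$$

with taxon-level random deviations $\varepsilon_{ki}$. The quadratic has
no mechanistic interpretation; it is the simplest unimodal form that is
*linear in its coefficients*, so the whole analysis stays inside the
`lme4` linear-mixed-model framework. $x$ enters through an orthonormal
polynomial basis (`build_orthogonal_basis()`, the `poly()` construction)
built **once per gradient on the union of observed levels and shared
across all stress conditions**. This matters twice over: orthogonality
decorrelates the three coefficients so they read as curve *height*
(intercept), *position* (linear) and *width* (quadratic); and sharing one
basis across conditions is what makes between-condition coefficient
contrasts meaningful. The sign convention fixes the linear column to
increase with $x$.

A categorical `stress` factor (control, each single added stressor, their
combination) can enter as a main effect only, interacting with the linear
term, or interacting with all polynomial terms. The default candidate grid
crosses {linear, quadratic} × {main, linear, full} stress structures ×
{intercept, intercept+linear, full} random structures — 18 descriptors
from the most complex interaction model down to a linear main-effects
model. All fits use **maximum likelihood** (not REML) so that AICc,
$\mathrm{AICc} = -2\ell + 2k + 2k(k+1)/(n-k-1)$ with $k$ the full
parameter count, is comparable across fixed structures; ties are broken by
fewer parameters. (For degree-1 models the "linear" and "full" stress
structures coincide; the duplicated pair simply ties.)

Singular random-effects fits are retried with a progressively simplified
random structure and flagged; a single-taxon dataset degrades to a
fixed-effects `lm()` with the singular flag set, so fixed effects are
always returned.

**Contrasts.** `pairwise_contrasts()` compares a composed coefficient
(e.g. the intercept under control vs. under an added stressor) between all
condition pairs, with standard errors from the fixed-effect covariance and
a t test on residual degrees of freedom $n - p_{fixed}$. Residual df is an
approximation chosen deliberately: it reproduces the large-integer df
style of reporting, whereas Satterthwaite-type corrections are out of
scope here. Raw and Holm-adjusted p values are both reported; no
adjustment is baked in because conventions differ between audiences.

## 3. Null models, Hedge's d and classification

At each gradient level $s$ of stressor A, with added stressor B (and
optionally C) fixed at their stressful levels, the additive null predicts
the combined growth rate

$$G_{AB} = G_{As} + G_{Bc} - G_{Ac} \quad (+\, G_{Cc} - G_{Ac}
\text{ for a third stressor}),$$

where the control statistics $G_{Ac}$, $G_{Bc}$, $G_{Cc}$ are all taken at
A's control level. Because growth rate cannot be negative, predictions
below zero are clamped to zero — deliberately *raising* the prediction so
that the bias runs against antagonism, not towards it. Clamping is applied
once, after the full sum (including any third-stressor term), and only to
the prediction: observed means are data and are never modified. The
multiplicative null multiplies relative effects,
$G_{Ac}(G_{As}/G_{Ac})(G_{Bc}/G_{Ac})$, and is undefined when
$G_{Ac} = 0$.

Deviations are standardized with bias-corrected Hedge's d,

$$d = J\,\frac{\bar{x}_{pred} - \bar{x}_{obs}}{s_{pooled}},\qquad
J = 1 - \frac{3}{4(n_{obs}+n_{pred}-2)-1},$$

$$\mathrm{var}(d) = \frac{n_{obs}+n_{pred}}{n_{obs}\,n_{pred}} +
\frac{d^2}{2(n_{obs}+n_{pred})},$$

with a normal-approximation 95 % CI ($\pm 1.96\sqrt{\mathrm{var}(d)}$; the
multiplier is configurable, and no df-based interval is attempted).
Classification follows the CI rule: a CI crossing zero is **additive**,
otherwise negative d is **antagonistic** and positive d **synergistic**.

Three constructions here were genuinely open and are resolved as follows:

* **Sign convention.** $d = (\text{predicted} - \text{observed})/s_{pooled}$,
  so a combined effect *more* detrimental than predicted (observed below
  prediction) gives positive d = synergism. Because every stressor in this
  setting reduces growth, a single global convention suffices and no
  per-case directional correction is applied.
* **Predicted-group variance.** The additive prediction is a linear
  combination of group means, so its variance is the sum of the squared
  coefficients times the group-mean variances (the $-2 G_{Ac}$ term of the
  three-way prediction contributes $4\,\mathrm{se}^2(G_{Ac})$); the
  multiplicative prediction uses the first-order delta method. A
  pseudo-standard deviation is back-formed as
  $\sqrt{\mathrm{var}(\bar{x}_{pred})\cdot n_{pred}}$ with $n_{pred}$ the
  (rounded mean) replicate count of the contributing groups, and pooled
  with the observed SD. This is the standard meta-analytic construction
  for comparing an observation to a derived prediction; it is a
  convention, and it is stated here prominently for that reason.
* **Zero-growth cells.** At extreme stress all replicates can be zero in
  both the observed group and the prediction, making d undefined (zero
  pooled SD). By default such zero–zero cells are classed additive with
  d = 0 — a prediction of no growth matched by an observation of no
  growth — under the `zero_zero_additive` flag; any other zero-variance
  cell is flagged and excluded from frequency counts with a logged count.

## 4. Effect-size trends and curve divergence

`fit_trend_model()` models Hedge's d along the gradient with penalized
cubic regression splines via `mgcv::gam` — the engine a practitioner
would reach for — with shrinkage (`bs = "cs"` and `select = TRUE`, REML
smoothing-parameter estimation) so the smooth is annihilated when d is
unrelated to the gradient. Four structures are compared by AICc (using the
model's effective degrees of freedom as $k$): intercept-only, one global
smooth, global smooth + taxon intercepts, and per-taxon smooths + taxon
intercepts. Per-taxon smooths use the factor-smooth (`bs = "fs"`) basis,
which shares a single smoothing parameter across taxa — the stable choice
when each taxon contributes only 7–8 assessable levels. The basis
dimension request is 10 and is automatically reduced to the number of
distinct gradient levels; smooth structures require at least 5 distinct
levels per taxon. Effect sizes enter unweighted by default (a
`weight_by_variance` option exists) because the modelled relationship is
between d itself and the gradient. An exactly constant d vector is a
degenerate input for REML and is returned directly as a flat fit with zero
smooth edf.

`curve_divergence()` evaluates, at each gradient value, the difference
between the predicted control curve and the predicted added-stressor curve
from one fitted model, and `divergence_effect_regression()` regresses the
observed effect size on that difference. Under the additive null the two
are linearly related by construction —
$\text{pred} - \text{obs} = [G_A(s) - G_{AB}(s)] + (G_{Bc} - G_{Ac})$ —
so the regression slope is positive and the fit tight whenever clamping is
rare; the end-to-end check in the test suite verifies slope > 0 and
R² > 0.9 on a constructed diverging-curves scenario.

## 5. The synthetic generator

The generator exists so every downstream stage can be validated against
known truth. Its ground-truth curve is a clamped parabola parameterized by
peak rate $r_{max}$ (h⁻¹), peak position $x_{opt}$ and half-width $w$
(gradient units, peak to zero crossing):
$r(x) = \max\{0, r_{eff}(1 - ((x - x_{eff})/w_{eff})^2)\}$. This family
was chosen over raw polynomial coefficients because each added stressor
can then modify the curve in the three interpretable directions — height
(`delta_height`), position (`delta_position`), width (`delta_width`) —
applied additively per added stressor. Taxon-level variation is drawn once
per taxon as independent centred Gaussians on $(r_{max}, x_{opt}, w)$; no
correlation structure is imposed, the simplest form consistent with the
random-coefficients assumption of the curve model. Replicate rates add
Gaussian noise and are floored at zero, mirroring the biological
constraint used by the null models.

Default design constants mirror the factorial plate layout the package
targets: 12 taxa, 3 replicates per condition, nine temperature levels
(15–47 °C, control 20 °C), eight pH levels (4–11, control 7.2), eight
salinity levels (0–35 g NaCl/L, control 0), a control plus two single
added stressors and their combination, and the 2 h/4 h OD sampling
schedule. Curve-shape and noise defaults ($r_{max} = 1.2$ h⁻¹, optimum
27 °C, half-width 17 °C, per-stressor height drop 0.25 h⁻¹, replicate
noise SD 0.05 h⁻¹, OD noise SD 0.02 on the log scale) are not dictated by
any dataset; they were fixed once at values typical of fast-growing
heterotrophic bacteria and kept.

What the generator does **not** emulate: plate spatial effects (edge
wells, evaporation), instrument drift, death phases after carrying
capacity, non-Gaussian replicate error, or correlated taxon deviations.
Replicate-level Gaussian error in particular is an assumption of
convenience, not a claim about real plates — so passing recovery tests
demonstrates correctness of the estimators under the stated model, not
robustness to every feature of real data.

## 6. Problem sizes and numerical tolerances in the test suite

The validation suite runs the full factorial design (12 × 4 × 9 × 3 =
1296 wells) for single fits, 100-replicate simulations for the power and
false-positive checks of the intercept contrast (at replicate noise SD
0.02), 100 noisy series for Gompertz recovery, and reduced designs (2–6
taxa, 6–7 levels) where only structure is being exercised. Noiseless
round-trips are asserted at 10⁻⁴ (Gompertz parameters) and 10⁻⁶ (curve
predictions); the oracle equivalence of the null-model and effect-size
arithmetic is asserted at 10⁻¹². The end-to-end diverging-curves scenario
uses replicate noise SD 0.01 rather than exactly zero: with literally
noiseless replicates every group has zero variance and Hedge's d is
undefined, so a small, fixed noise keeps the check deterministic in
character while leaving d computable.

## 7. Known limitations

* Residual-df t tests for contrasts are approximate; with few taxa and
  strong random structure they are anti-conservative relative to
  Satterthwaite-style corrections.
* The AICc parameter count for mixed models counts variance components as
  estimated parameters (the `logLik` df), which is itself a convention.
* The multiplicative null's variance uses a first-order delta method and
  degrades near $G_{Ac} \to 0$.
* Trend-model p values for smooths are deliberately not reported; only
  structure selection and fitted shapes are in scope.
* The deposited-archive loader maps long-format rate tables by a
  user-supplied column map; it does not parse raw plate-reader exports.
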