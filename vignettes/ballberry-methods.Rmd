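---
title: "Modelling stomatal conductance and leaf water use efficiency under soil water deficit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling stomatal conductance and leaf water use efficiency under soil water deficit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ballberry)
```

## The model

The Ball-Berry model relates stomatal conductance to water vapour,
$g_s$ (mol m⁻² s⁻¹), linearly to the *Ball index* — the product of net
photosynthetic rate $P_n$ (µmol m⁻² s⁻¹) and leaf-surface relative
humidity $h_s$, divided by the leaf-surface CO₂ mole fraction $C_s$
(µmol mol⁻¹):

$$g_s = m \frac{P_n h_s}{C_s} + g_0 .$$

$m$ (dimensionless) is the stomatal sensitivity slope and $g_0$
(mol m⁻² s⁻¹) the residual conductance at zero assimilation. The model is
empirical but remarkably robust for well-watered plants; its weakness is
that $m$ is not constant under soil water deficit. This package implements
a variant in which the slope decays exponentially with the mean soil water
potential of the whole root zone, $\Psi_s$ (MPa, ≤ 0):

$$m = m_i \, e^{-\beta \Psi_s},$$

where $m_i$ is the slope at zero water deficit and $\beta$ (MPa⁻¹) a decay
constant. Fitted $\beta$ is negative, so the slope — and with it $g_s$ —
shrinks as the soil dries. Using the *mean* root-zone potential (rather
than the potential of the driest compartment) matters for split-root
irrigation, where the two halves of the root system experience very
different water status: root-sourced ABA signalling integrates over the
root zone, and the whole-zone mean is its best single-variable proxy.

### Closing the humidity loop

$h_s$ and $C_s$ are leaf-surface quantities inside the boundary layer.
With boundary-layer conductance $g_b$ (mol m⁻² s⁻¹),

$$C_s = C_a - \frac{1.37 P_n}{g_b}, \qquad
  h_s = \frac{e_a/e_i + g_s/g_b}{1 + g_s/g_b},$$

where $e_a$ is the air vapour pressure, $e_i$ the saturation vapour
pressure at leaf temperature (Magnus form,
$e_i = 6.11\,e^{7.5 \ln 10\, T/(T+237.3)}$ hPa), and 1.37 the
water-to-CO₂ diffusivity ratio across the boundary layer. Because $h_s$
depends on $g_s$, the model is an implicit fixed-point problem.
Substituting the humidity balance into the conductance relation gives a
quadratic $A g_s^2 + B g_s + C = 0$ with

$$A = C_s/g_b,\quad
  B = C_s - g_0 C_s/g_b - mP_n/g_b,\quad
  C = -(g_0 C_s + m P_n e_a/e_i),$$

solved in closed form by `solve_gs()`, which always takes the
$(-B + \sqrt{B^2-4AC})/(2A)$ root. The test suite verifies on a thousand
random driver draws that this root agrees with an independently written
damped fixed-point iteration to better than $10^{-8}$ relative, satisfies
the fixed-point identity to $10^{-9}$, and collapses to the closed form
$m P_n (e_a/e_i)/C_a + g_0$ as $g_b \to \infty$.

Downstream quantities are transpiration
$T_r = (e_i-e_a)/\big(P_{atm}(1/g_s + 1/g_b)\big)$ (reported in
mmol m⁻² s⁻¹; the typeset source of this expression is ambiguous and was
resolved by dimensional analysis so that WUE is exactly its reciprocal
times $P_n$) and leaf water use efficiency $WUE = P_n/T_r$
(µmol CO₂ per mmol H₂O), so $WUE \cdot T_r = P_n$ holds identically on
every valid record. $P_n$ is always an *observed driver*, never modelled:
coupling a photosynthesis model would entangle the very $P_n$–$g_s$
correlation the conductance model is meant to explain. Units follow
standard gas-exchange practice: $P_n$ in µmol m⁻² s⁻¹ (a source that
prints mmol for values like 15.3 is treating the unit loosely — µmol is
the only dimensionally consistent reading against $C_s$ in ppm), vapour
pressures in hPa, $\Psi_s$ in MPa, conductances in mol m⁻² s⁻¹.

### Degenerate records

With $g_0 < 0$ (which empirical fits produce) the "+√" root can be
non-positive at a small Ball index, and the discriminant can in principle
go negative. Such records are flagged `valid = FALSE` and excluded from
residual sums and metrics with a reported count — never clipped and never
silently dropped, since no principled clipping rule exists for them.

## Parameter estimation

`fit_bb()` estimates $(m, g_0)$ or $(m_i, g_0, \beta)$ by minimising
$\sum (g_s^{obs} - g_s^{pred})^2$ with Levenberg–Marquardt least squares.
Three fixed starting points guard against local minima; the fit is fully
deterministic given the data. Confidence bounds are asymptotic Wald
intervals — $t$-quantile at $n-p$ degrees of freedom, covariance
$\hat\sigma^2 (J^\top J)^{-1}$ with $J$ the central-difference Jacobian at
the optimum. (Reference interval pairs of the form "(low ~ high)" are read
as 95% intervals of this kind.) No sign is forced on $\beta$ or $g_0$.
Two identifiability gates reject ill-posed problems before optimisation:
a constant Ball index, and — for the modified variant — constant $\Psi_s$,
which confounds $\beta$ with $m_i$ exactly. Over 200 simulated
parameterisation experiments the 95% intervals cover the generating
$(m_i, g_0, \beta)$ at 94–96%, comfortably nominal.

`goodness()` scores observed against predicted values with the squared
Pearson correlation $r^2$, MAE and RMSE. `wue_vpd_ancova()` reproduces the
classical ANCOVA workflow for comparing WUE–VPD regression lines across
irrigation treatments: per-group OLS lines with standard errors and
significance stars, an F-test of slope homogeneity (full-interaction vs
common-slope model), and — only when a common slope is tenable at
$\alpha = 0.05$ — pairwise comparisons of adjusted intercepts summarised
as compact letters. Pairwise tests are unadjusted by default, matching the
usual SAS-style output this table layout comes from; an adjustment option
is exposed. The letter display uses a small insert-absorb implementation;
its type-I behaviour is checked by simulation (identical lines share a
letter in ~95% of replicates).

VPD is computed from leaf temperature, $VPD = (e_i - e_a)/10$ kPa. Whether
the original measurements referenced air or leaf temperature for the
"atmospheric" VPD is not documented; leaf temperature is the only
temperature in the data model, and in a climate-controlled chamber the two
are within a fraction of a degree.

## The synthetic experiments

No field data ship with the package. Instead, two generators emulate the
*statistical structure* of the greenhouse experiments the method is built
for, so that estimation and validation are testable end to end. They make
no attempt to reproduce any measured point cloud.

**Water retention.** Both substrates are van Genuchten curves,
$\Psi(\theta) = -(1/\alpha)\,[S^{-1/(1-1/n)} - 1]^{1/n}$ with
$S = (\theta-\theta_r)/(\theta_s-\theta_r)$, with exact closed-form
inverse. Because the original retention measurements are not tabulated,
each preset is calibrated (1-D root finding on the alpha-free anchor
ratio) to pass through two anchor points that *are* stated: sand through
(θ = 0.18, ψ = −0.0008 MPa) and (0.06, −0.398) — the full-irrigation
target and the drying-side switch threshold; peat through (0.50, −0.01)
and (0.15, −0.55) — the wet start and dry end of a 5-day pot dry-down.
Residual/saturated contents are fixed at 0.10/0.60 (peat) and 0.045/0.38
(sand), typical textbook values for those media.

**Experiment I (parameterisation).** 5 plants × 5 days of progressive
drying in 1.5 L peat pots at 400 or 800 ppm CO₂. Each day the pot loses
water equal to the forward-model transpiration times an effective-leaf-area
constant, auto-calibrated (root finding, deterministic) so the noise-free
trajectory ends at $\Psi_s = -0.53$ MPa (400 ppm) or $-0.61$ MPa
(800 ppm). $P_n$ declines as $P_{n,wet} e^{k\Psi_s}$ with
$P_{n,wet} = 15.3$ and $18.3$ µmol m⁻² s⁻¹ and $k$ calibrated from the
reported wet/dry endpoint pairs ($k \approx 4.42$ and $2.63$ MPa⁻¹), so
the dry-down ends at about 10% (400 ppm) and 21% (800 ppm) of the wet
rate. True conductance comes from `solve_gs()` under the reference
parameter sets (`tomato_params()`): at 400 ppm
$m_i = 33.43, g_0 = 0.019, \beta = -1.98$; at 800 ppm
$m_i = 41.55, g_0 = -0.004, \beta = -2.07$ (original-variant sets
analogous).

**Experiment II (validation).** 40 days, 10 L split-root pots of sand,
three regimes: FI refills both columns to 18 vol-% daily; PRI waters one
column with 70% of the FI daily amount until the dry column reaches
6 vol-%, then switches sides; DI splits the PRI amount evenly. Uptake is
forward-model transpiration at the *mean* column potential — the same
mean-$\Psi_s$ premise as the conductance model — split between columns in
proportion to plant-available water, with drainage above field capacity.
The uptake scale is auto-calibrated so a PRI run completes 5 side switches
in 40 days (a bisection on the discrete switch count). The emergent
behaviour then matches the reported water regimes without further tuning:
FI columns stay above −0.001 MPa, DI settles where uptake balances the
70% ration (mean $\Psi_s$ ∈ [−0.08, −0.001] MPa, inside the reported
−0.112…−0.001 band), and the PRI dry column spans −0.0008 to about −0.39
MPa. 48 observations per regime: 24 evenly spaced measurement days × 2
plants.

**Noise model.** The sources state no measurement-error model, so one set
of values was chosen once, at magnitudes a gas-exchange practitioner would
recognise, and kept: additive Gaussian sd 0.02 mol m⁻² s⁻¹ on observed
$g_s$ (truncated positive by redraw), multiplicative 5% cv on $P_n$, leaf
temperature N(20, 0.5) °C (the chamber setpoint), air vapour pressure
N(14, 1) hPa (≈60% RH at 20 °C). Observed $g_s$ is generated at the
*observed* (noisy) drivers, so the noise-free limit is exactly
recoverable and fitting is free of errors-in-variables bias. The seed
controls only noise; the deterministic driver schedules (water balance,
$P_n$ decline) are identical across seeds. What these generators do *not*
emulate: day-to-day weather variation, pot evaporation (no data exist for
it), leaf-to-leaf parameter heterogeneity, and CO₂-dependent initial
conductance ordering beyond what the reference parameter sets imply.
Passing tests therefore demonstrate correctness of the machinery and
recoverability under realistic noise — not model adequacy for any real
dataset.

## Problem sizes and numerical choices

Simulated studies use the experiment-scale sizes throughout: n = 25 for
parameterisation fits, n = 48 per validation regime, 200 replicates for
interval-coverage checks, 1000 for the solver-equivalence and ANCOVA
type-I simulations. Solver and identity tolerances are fixed (quadratic
vs iteration $10^{-8}$; fixed-point identity $10^{-9}$; water balance
$10^{-12}$; optimiser `ftol`/`ptol` $10^{-12}$); all arithmetic is double
precision. Ties and degeneracies fail loudly: infeasible irrigation
configs, unreachable cycle targets, rank-deficient designs and
supersaturated humidity inputs all raise errors rather than warnings.

## A worked chain

```{r}
p <- tomato_params(400, "modified")
exp1 <- simulate_progressive_drying(drying_config(co2 = 400, seed = 1))
fit <- fit_bb(exp1, "modified")
fit
pri <- simulate_split_root(split_root_config(co2 = 400, treatment = "PRI",
                                             seed = 2))
v_mod <- validate_bb(fit$params, pri)
v_mod$metrics
```

## Known limitations

The slope modification is empirical: $\beta$ absorbs whatever makes
stomata close with drying soil (ABA signalling, hydraulics) and transfers
across species or substrates only by refitting. The asymptotic intervals
rely on local linearisation; at n = 25 they are well calibrated in
simulation, but bootstrap intervals would be preferable far from the
reference conditions. The generators share one leaf per plant and one
environmental schedule per day; they cannot exhibit between-leaf variance
components, so mixed-effects extensions are untestable against them. And
$r^2$, MAE and RMSE computed on synthetic data say nothing about the
field predictive skill of the model — only parameter-recovery targets and
structural identities are meaningful acceptance evidence here.
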