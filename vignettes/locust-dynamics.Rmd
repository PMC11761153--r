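---
title: "Temperature-driven dual-phase locust dynamics: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temperature-driven dual-phase locust dynamics: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(locustdyn)
```

## The model

Desert locust (*Schistocerca gregaria*) populations alternate between a
cryptic, low-density *solitarious* phase and an aggregating *gregarious*
phase (hopper *bands*, adult *swarms*). `locustdyn` implements a
stage-structured compartmental model with five state variables — eggs $E$,
solitarious hoppers $H$, gregarious bands $B$, solitarious adults $S$ and
gregarious swarms $G$, all densities per square metre:

$$
\begin{aligned}
E' &= (1-\eta)\,\phi\,(1 - E/K)\,(S + \psi G) - (\sigma + \mu_e)\,E\\
H' &= \theta\sigma E - (\gamma_h + \mu_h)\,H\\
B' &= (1-\theta)\sigma E - (\gamma_b + \mu_b)\,B\\
S' &= \gamma_h H + \beta_2 G - (\beta_1 + \mu_s)\,S\\
G' &= \gamma_b B + \beta_1 S - (\beta_2 + \mu_g)\,G
\end{aligned}
$$

Oviposition is logistic in the egg density (carrying capacity $K$ of moist
sandy soil), only females ($1-\eta$) lay, and gregarious females lay at a
reduced rate ($\psi < 1$). Hatchlings split $\theta : 1-\theta$ between the
phases; adults exchange phase by gregarisation ($\beta_1$) and dissociation
($\beta_2$). In the seasonally forced variant every vital rate except
$\theta$, $\beta_1$, $\beta_2$, $\psi$, $\eta$, $K$ may depend on the
instantaneous temperature.

Key assumptions worth keeping in mind: the habitat is homogeneously mixed
(no spatial structure or migration), the sex ratio is constant, soil
moisture is folded into temperature (egg rates respond to air temperature
as a proxy for soil temperature), and phase transition happens only in the
adult stage.

## Baseline parameters and their derivations

`locust_params()` carries the baseline constants; `derive_baseline_params()`
recomputes the derived entries from primary life-history quantities and
cross-checks them to four decimals:

* band mortality from the instar schedule (70/20/10/10/10 % instar losses,
  5 % per moult, four moults): `aggregate_stage_mortality()` gives 0.8575;
* solitarious hopper mortality via the published one-fewer-moult scaling
  $\mu_h = \mu_b \times 0.95 \times 0.9 = 0.7332$;
* fecundity bounds from eggs per generation over a 3–5 month lifespan
  (400 eggs solitarious, 140 gregarious; 30-day months), hence
  $\psi = 140/400 = 0.35$;
* $K = 160$ eggs/pod $\times$ 500 pods/m² $= 80{,}000$;
* adult mortality bounds $1/150$–$1/90$ day⁻¹.

Two editorial choices are deliberate. First, $\beta_1$, $\beta_2$ are
tabulated as 0.25 hr⁻¹ in the source while every other rate is per day;
the package treats 0.25 as a daily rate for dimensional consistency, with
`beta_unit = "per_hour"` available to apply the ×24 conversion instead.
Second, the source text at one point assigns the larger maximum fecundity
(4.4444) to gregarious females, contradicting its own derivation (400 eggs
for solitarious females vs 140); the package follows the derivation:
solitarious $E_{\max} = 4.4444$, gregarious $E_{\max} = 1.5556$.

## Thermal response curves

Four families cover the temperature-dependent rates
(`thermal_curve()`, `fitted_thermal_curve()`):

| rate | family | defaults (units: °C, day⁻¹) |
|---|---|---|
| fecundity $\phi(T)$ | Gaussian | $E_{\max}$ 4.4444 (sol.) / 1.5556 (greg.), $T_{opt}$ 30, $T_w$ 8 |
| hatching $\sigma(T)$ | Allahyari | $P$ 0.2658, $n$ 1.5818, $m$ 0.5, limits 15.1–42.9187 |
| development $\gamma_h, \gamma_b$ | Allahyari | $P$ 0.1192, $n$ 1.3176, $m$ 0.5, limits 15–45.012 |
| egg mortality $\mu_e(T)$ | lethal window | $M$ 1.19 (sol.) / 0.91 (greg.), $Q$ 1.5 |
| hopper mortality $\mu_h, \mu_b$ | lethal window | $M$ 0.1525 / 0.282, $Q$ 2, limits 15–35 |
| adult mortality $\mu_s, \mu_g$ | anchored window | baselines 0.0083 / 0.0111, limits 20–40 |

The Allahyari curve $P x^n (1 - x^m)$, $x = (T - T_{\min})/(T_{\max} -
T_{\min})$, is the standard unimodal development-rate form between lethal
limits; both hopper phases share one fitted development curve because only
one was fitted in the source (override per phase if desired).

The lethal-window mortality expression as printed,
$1 - M\exp\!\big((1+e^{(T_{\min}-T)/Q})(1+e^{(T-T_{\max})/Q})\big)$, is
negative in the window interior and inverted in shape (the exponent is at
least 1). The package's default `normalized` variant,
$\mathrm{clamp}\big(1 - M\exp\!\big(1 -
(1+e^{(T_{\min}-T)/Q})(1+e^{(T-T_{\max})/Q})\big),\,0,\,1\big)$, restores
the U-shape (interior level $\approx 1 - M$, saturating at 1 beyond the
lethal bounds) while preserving the role of the printed constants — in
particular the ordering that gregarious eggs ($M = 0.91$) die faster than
solitarious ones ($M = 1.19$, clamped interior 0). The verbatim
`as_printed` variant is retained as a diagnostic and flags out-of-range
values. Egg-mortality lethal bounds are not published; the defaults reuse
the egg-viability limits of the hatching fit (15.1 / 42.9187 °C),
configurable.

No functional form is published for adult mortality; the package uses a
declared modelling choice, `adult_mortality()`: the $M = 1$ normalized
window rescaled to zero at its interior minimum, then anchored so the
minimum equals the published baseline daily mortality and the curve
saturates at 1 beyond the 20–40 °C activity range.

## Seasonal forcing

`temperature_forcing()` implements
$T(t) = T_0\big[1 + T_1\cos\big(\tfrac{2\pi}{365}(\omega t +
\kappa)\big)\big]$ (multiplicative, the literal published form, default)
and an additive variant $T_0 + T_1\cos(\cdot)$. The distinction matters
because the published simulation setting "$T_1 = 2$ °C" with the
multiplicative form implies a ±200 % swing (−20 to 60 °C at $T_0 = 20$);
the °C unit suggests the amplitude was meant additively. Both variants are
exposed; the packaged figure-reproduction experiments use the additive
variant and record it in their run metadata. Whether the original
simulations used the multiplicative form literally is unknowable from the
text; the package does not guess silently.

## Thresholds

`offspring_number()` evaluates the closed-form basic offspring number
$N_0 = N_{0S} + N_{0G}$ (expected female offspring per female; extinction
below 1, persistence above 1), and `offspring_number_ngm()` independently
computes the spectral radius of $R V^{-1}$ from the assembled recruitment
and transfer matrices. The two routes agree to $10^{-10}$ relative on
randomized draws (tested), and the package treats the matrix route as the
oracle for the algebra.

```{r}
p_ext <- locust_params(phi = 1.75)
offspring_number(p_ext)
offspring_number_ngm(p_ext)
```

Two caveats discovered while validating against the source:

* The published captions for the extinction and persistence simulations
  quote $N_0 = 0.2636$ and $16.2066$; evaluating the published closed form
  (or the matrix oracle — they agree) with the published parameter values
  and the stated overrides gives 0.3624 and 14.1865. No single
  reinterpretation of the inputs explains both captions (the two
  discrepancies go in opposite directions), so the package reports its own
  computed values from both routes and documents the mismatch rather than
  forcing agreement.
* The published $\phi^*$ display swaps the $\gamma_h$/$\gamma_b$
  subscripts relative to what solving $N_0 = 1$ actually yields.
  `phi_star()` implements the algebraically consistent grouping and
  enforces the defining identity $N_0(\phi^*) = 1$ at call time (a warning
  fires if it is violated beyond $10^{-8}$).

`nontrivial_equilibrium()` uses $E^{**} = K(1 - 1/N_0)$, the hopper
proportionalities, and solves the 2×2 adult linear balance directly (the
published adult-equilibrium expressions are typographically garbled); the
zero-residual property of the ODE right-hand side, not the printed
algebra, is the ground truth and is checked on every call.
`stability_report()` evaluates the analytic Jacobian spectrum (validated
against finite differences in the tests) and cross-checks the origin's
verdict against the $N_0$ rule.

### Bifurcation at the threshold

`bifurcation_coefficients()` performs the center-manifold analysis at
$\phi = \phi^*$: the right and left null vectors $u$, $v$ of the Jacobian
(normalized to fifth component 1) give
$a = -\tfrac{2(1-\eta)\phi^*}{K} v_1 u_1 (u_4 + \psi u_5)$ and
$b = (1-\eta) v_1 (u_4 + \psi u_5)$, always of opposite signs. The source
proposes a sign rule $\mathrm{sign}(v_1) = \mathrm{sign}\big(
(\beta_2\mu_s - \beta_1\mu_g)/(c_5 - \psi c_4)\big)$ that would permit
$v_1 < 0$; in fact the Jacobian at $\phi^*$ is an irreducible Metzler
matrix whose dominant eigenvalue is the zero eigenvalue, so by
Perron–Frobenius both null vectors are strictly positive: $v_1 > 0$,
$a < 0 < b$, and the bifurcation is always forward (supercritical)
whenever the adult balance $c_4 c_5 - \beta_1\beta_2 > 0$ holds — which it
always does for positive adult mortalities, since
$c_4 c_5 - \beta_1\beta_2 = \mu_s c_5 + \beta_1 \mu_g$. One can verify
directly from $vJ = 0$ that
$v_4 = v_5 (c_5 + \psi\beta_1)/(\psi c_4 + \beta_2) > 0$ and $v_1 \propto
c_4 c_5 - \beta_1\beta_2$. The report exposes both the numeric sign (used
for classification) and the published rule's sign, and warns when they
disagree. The exactly symmetric case $\beta_2\mu_s = \beta_1\mu_g$ is
flagged as a degenerate boundary.

## Periodic threshold

For the forced system, `periodic_offspring_ratio()` computes the basic
offspring ratio $N_0^\omega$ — the spectral radius of the next-generation
operator on periodic functions — through the standard monodromy
characterization: integrate $W' = [-V(t) + F(t)/\lambda]W$, $W(0) = I$,
over one forcing period and find the $\lambda$ at which $\rho(W(\omega))
= 1$ by bracketed root finding (tolerance $10^{-6}$; integration
tolerances $10^{-10}$/$10^{-12}$). The bracket expands outward from
$\lambda = 1$ because evaluating far below the root overflows the
monodromy (growth $\sim e^{F\omega/\lambda}$). A direct collocation
discretization of the integral operator was considered and rejected: the
monodromy route is standard, well conditioned and cheap at this dimension.
With zero-amplitude forcing the ratio reproduces the autonomous $N_0$ to
$10^{-6}$ relative; the sign of $N_0^\omega - 1$ agrees with the Floquet
stability of the unscaled linearization (both tested). No numeric
$N_0^\omega$ is published, so only these structural properties are
checkable.

## Curve fitting and the synthetic-data generator

The temperature-versus-rate tables behind the published fits are not
printed, so `generate_fixture_table()` stands in: it samples a known curve
on a grid and adds zero-truncated Gaussian noise under a mandatory seed.
This emulates the *design* of such assay tables (a temperature grid
spanning the viability window, homoscedastic rate-space noise); it does
not emulate replicate structure, heteroscedasticity, or digitization
error of real assay data, so recovery results demonstrate correctness of
the estimator, not field accuracy of the published parameters.

`fit_thermal_curve()` minimizes rate-space residuals (duration-space
fitting was considered; rate space matches how the curves enter the
model) with box-constrained Levenberg–Marquardt, data-driven starting
values (lethal bounds bracketing the observed support, scale matched to
the observed maximum) and a small multistart. Noiseless fixtures are
recovered to $10^{-4}$ relative or better. At realistic noise
(sd 0.005, 30 points) the three-parameter Gaussian family recovers its
parameters to well under 5 % median relative error, but the
four-parameter Allahyari fit (with $m$ fixed at 0.5) has a flat
$P$–$n$–$T_{\min}$ likelihood ridge: the optimizer routinely finds
parameter combinations with *lower* SSE than the generating truth, so
individual parameters can wander by ~10 % even though the fitted curve
stays within three noise standard deviations of the truth everywhere.
The tests therefore assert parameter recovery for the Gaussian family and
predictive (rate-space) recovery for the Allahyari family.

## Sensitivity analysis

`prcc_offspring_number()` draws a Latin hypercube sample
(`lhs_sample()`, one draw per equal-probability bin, seeded) over the
published ranges — parameters without a published range ($\psi$, $\mu_h$,
$\mu_b$) get ±20 % of baseline and are flagged as assumed — and computes
partial rank correlation coefficients of the closed-form $N_0$
(`prcc()`: rank-transform everything, correlate the two residual vectors
after regressing out all other parameters). The published bar heights are
not numeric, so validation is structural: PRCC signs must match the
analytic monotonicity of $N_0$ (increasing in $\phi, \psi, \sigma,
\gamma_h, \gamma_b$; decreasing in $\eta, \mu_e, \mu_h, \mu_b, \mu_s,
\mu_g$; independent of $K$, whose coefficient must shrink as
$3/\sqrt{n}$). The default sample size is 1000. Trajectory-based
sensitivity under fluctuating temperature is out of scope; the response is
always $N_0$.

## Numerical choices

* **Integrator**: adaptive Dormand–Prince 4(5) (`deSolve::ode`,
  `method = "ode45"`), rtol $10^{-8}$, atol $10^{-10}$, configurable. The
  egg logistic term is evaluated as written even if $E$ transiently
  exceeds $K$ (the term then pushes $E$ back down); no hard cap.
* **Negativity guard**: returned trajectories are clipped to $\ge 0$;
  dips beyond $10^{-9} \times \max(1, \max(\text{initial}))$ — i.e.
  beyond rounding noise at the problem scale of $K = 8\times10^4$ — abort
  with a diagnostic instead of being silently clipped.
* **Stability margin**: "stable" requires the largest eigenvalue real
  part below $-10^{-9}$.
* **Null vectors**: via SVD, with a simplicity check on the zero singular
  value; degenerate (non-simple) zero eigenvalues are an error.
* **Initial conditions** for the packaged scenarios are not published;
  the defaults spread several positive states across fractions of $K$ and
  are recorded in run metadata.
* **Problem sizes** used by the test suite: 1000 random parameter draws
  for the oracle-equivalence check, 200 for threshold/stability
  consistency, 4000-day horizons for extinction runs, 2000 days for
  convergence to the positive equilibrium, ten-period horizons for
  asymptotic periodicity, three randomized periodic systems for the
  Floquet consistency check, and ten Monte-Carlo seeds for noisy-fit
  recovery.

## Known limitations

* No spatial structure, migration, rainfall, or control interventions.
* Phase transition only in the adult stage, with density-independent
  rates $\beta_1$, $\beta_2$.
* The adult thermal-mortality curve is a declared package choice (no
  published form); conclusions sensitive to its shape should be checked
  against alternatives via the curve configuration.
* The periodic ratio is computed for the linearization at extinction; it
  classifies invasion/extinction, not the amplitude of established
  periodic orbits.
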