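# locustdyn

Temperature-driven population dynamics of the desert locust
(*Schistocerca gregaria*), for quantitative ecologists and pest-outbreak
modellers. The desert locust switches between a cryptic **solitarious**
phase and an aggregating **gregarious** phase (hopper *bands*, adult
*swarms*); outbreaks hinge on temperature, which governs egg hatching,
hopper development, mortality and fecundity. `locustdyn` provides a
stage-structured, dual-phase compartmental model of these dynamics as a
reusable simulator and analysis toolkit.

## The model

Five compartments — eggs $E$, solitarious hoppers $H$, bands $B$,
solitarious adults $S$, swarms $G$ (densities per m²):

$$
\begin{aligned}
E' &= (1-\eta)\,\phi\,(1 - E/K)\,(S + \psi G) - (\sigma + \mu_e)E\\
H' &= \theta\sigma E - (\gamma_h + \mu_h)H, \qquad
B' = (1-\theta)\sigma E - (\gamma_b + \mu_b)B\\
S' &= \gamma_h H + \beta_2 G - (\beta_1 + \mu_s)S, \qquad
G' = \gamma_b B + \beta_1 S - (\beta_2 + \mu_g)G
\end{aligned}
$$

In the seasonally forced variant the vital rates follow thermal response
curves (Gaussian fecundity, Allahyari development, lethal-window
mortality) driven by a cosine temperature signal
$T(t) = T_0[1 + T_1\cos(\tfrac{2\pi}{365}(\omega t + \kappa))]$.

The central threshold quantity is the **basic offspring number**
$N_0 = N_{0S} + N_{0G}$ — the expected lifetime female offspring per
female, the spectral radius of the next-generation matrix $RV^{-1}$ —
with extinction below 1 and persistence above 1. The package computes it
by closed form and independently by the matrix spectral radius, plus the
critical egg-laying rate $\phi^*$, equilibria and their Jacobian
stability, transcritical bifurcation coefficients, a periodic (Floquet)
offspring ratio $N_0^\omega$ for the forced system, and Latin-hypercube /
PRCC sensitivity analysis of $N_0$.

## Worked example

A persistence scenario (high fecundity, reduced hopper mortality):

```r
library(locustdyn)
p <- locust_params(phi = 25, mu_h = 0.25, mu_b = 0.3)

offspring_number(p)
#> Basic offspring number N0 = 14.1865 (solitarious 10.5651 + gregarious 3.6214)
```

$N_0 > 1$, so the population persists: there is a positive equilibrium,

```r
round(nontrivial_equilibrium(p), 1)
#>       E       H       B       S       G
#> 74360.8 12490.4  5730.1 24398.6 23894.6
```

and simulation from any positive initial state converges to it:

```r
tr <- simulate_locusts(c(1000, 0, 0, 10, 10), p, times = seq(0, 2000, 100))
round(tail(tr, 3), 1)
#>    t_days       E       H      B       S       G        N
#> 19   1800 74360.8 12490.4 5730.1 24398.6 23894.6 140874.5
#> 20   1900 74360.8 12490.4 5730.1 24398.6 23894.5 140874.5
#> 21   2000 74360.8 12490.4 5730.1 24398.6 23894.6 140874.5
```

Eggs settle at $K(1 - 1/N_0) \approx 74{,}361$ per m²; about half the
adults are in the gregarious (swarming) phase because the gregarisation
and dissociation rates are equal at baseline.

Which parameters drive $N_0$? Latin-hypercube sampling over the published
ranges plus partial rank correlation:

```r
prcc_offspring_number(n = 1000, seed = 42)
#> PRCC against N0 (n = 1000):
#>  parameter    prcc
#>       mu_e -0.8928
#>        phi  0.8637
#>      sigma  0.8623
#>    gamma_b  0.4113
#>        eta -0.3156
#>  ...
#>          K  0.0321
```

Egg mortality, fecundity and hatching rate dominate; the egg carrying
capacity $K$ provably does not enter $N_0$ and its coefficient is
statistical noise.

Seasonal forcing and the periodic threshold:

```r
ts  <- build_thermal_param_set(list(sigma = fitted_thermal_curve("sigma")))
f   <- temperature_forcing(30, 5, omega = 2, variant = "additive")
lin <- periodic_linearization(ts, f)
periodic_offspring_ratio(lin)   # N0_omega for the forced system
```

## Command line

A thin CLI over the package functions lives at `inst/cli/locustdyn.R`:

```sh
Rscript inst/cli/locustdyn.R threshold --out-dir out/
Rscript inst/cli/locustdyn.R experiment --config run.yaml --out-dir out/
Rscript inst/cli/locustdyn.R prcc --seed 7 --n 1000 --out-dir out/
```

Run configurations are YAML (`parse_config()` documents the schema);
trajectories are written as CSV, scalar reports as JSON.
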