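# lvfit

Fitting generalized Lotka–Volterra interaction models to abundance time
series of one or more species — for ecologists, students, and anyone who
needs interpretable growth rates and interaction coefficients from
classic microcosm-style data.

## The model and the method

The package fits

$$\frac{dN_i}{dt} = N_i\Big(r_i + \sum_j a_{ij} N_j\Big)$$

where $r_i$ is species $i$'s intrinsic growth rate, $a_{ii}$ its
self-limitation and $a_{ij}$ the per-capita effect of species $j$ on
species $i$ (`A[i, j]`, column acts on row). For one species this is
logistic growth with carrying capacity $K = -r/a_{ii}$.

Fitting is two-stage. Dividing by $N_i$ linearizes the model,
$dN_i/(N_i\,dt) = r_i + \sum_j a_{ij} N_j$, so per-capita growth rates
(log ratios of successive abundances over the elapsed time) are
regressed on abundances by OLS: intercept $\to r_i$, slopes
$\to a_{ij}$. These estimates seed a sign-constrained Nelder–Mead +
BFGS search over log-transformed parameter magnitudes that tunes the
parameters (including initial abundances) so that fully **simulated**
trajectories match the observations, compared on mean-standardized
abundances. Approximate standard errors come from the numerically
differentiated Hessian in log-parameter space, and fits are scored by an
$R^2$-like index ($1$ = perfect, $\le 0$ = no better than the observed
mean), per species and pooled. See the vignette
(`vignettes/lv-fitting-methods.Rmd`) for the full account.

## Worked example

Generate a noise-free logistic monoculture (the preset uses published
fitted values for *Paramecium caudatum* grown alone) and run the full
pipeline:

```r
library(lvfit)
dat <- generate_observations(lv_preset("logistic_monoculture", noise_sd = 0))
fit <- fit_lv(dat$observations)
fit
```

```
Lotka-Volterra fit (1 species, 25 observations)
N0: P_caudatum=0.22 (± 2.8e-09)
r : P_caudatum=0.96 (± 1.8e-09)
A  (column acts on row):
           P_caudatum
P_caudatum -0.005 (± 9.9e-12)
K : 192
objective: 3.33826e-17 (start 0.0394831 ) [converged]
Goodness of fit (1 = perfect, <= 0 = poor):
  P_caudatum     1.0000  (n = 25)
  total          1.0000
```

Reading the output: the population starts near volume 0.22, grows at
0.96/day when rare, limits its own growth ($a_{ii} < 0$), and levels off
at $K = -r/a_{ii} = 192$ volume units; with noise-free input the
optimizer reduces the objective from its regression-based start to
~1e-17 and the goodness of fit is exactly 1. On real (noisy) data the
standard errors become informative and the GOF drops below 1.

Multi-species fits work the same way — `fit_lv()` returns the
interaction matrix whose sign pattern identifies competition
($a_{ij}, a_{ji} < 0$), mutualism ($+,+$) or predation ($-,+$) — and
constraints such as "no direct wolf–fir interaction" can be imposed via
`lv_mask()` / a YAML constraints file.

A thin command-line front end covers the same pipeline:

```sh
Rscript inst/cli/lv.R generate --preset paramecium_competition --seed 1 --out data.csv
Rscript inst/cli/lv.R fit --input data.csv --out fit.json --trajectory-out traj.csv
```

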