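# flowintern

Quantifies **cell-to-cell variability in receptor-mediated internalization**
from flow-cytometry snapshot data.

Internalization assays label material (here, an anti-transferrin-receptor
antibody) with fluorescent probes and measure per-cell fluorescence at a
handful of incubation times, in quenched aliquots (surface signal switched
off) and unquenched ones. The data are snapshots — each cell is measured
once — and the observed spread mixes three things: kinetics, genuine
biological heterogeneity, and instrument noise. `flowintern` models all
three layers generatively and calibrates them together:

1. **Kinetics.** A linear four-compartment model per cell — internal
   transferrin-bound receptors *T*, surface antibody-bound complexes *S*,
   endocytosed complexes *E*, and accumulated free antibody *F*:

   dT/dt = −βT, dS/dt = βT − λS + pβE, dE/dt = λS − pβE, dF/dt = pβE,

   with internalization rate λ, recycling rate β, disassociation probability
   p, started from the receptor equilibrium S(0) = β/(λ+β). Solved in exact
   closed form, vectorized over cells.

2. **Heterogeneity.** Per-cell properties (R, λ, β) — relative receptor
   count and the two rates — follow a shifted log-normal (E(R) = 1 enforced)
   and two shifted-Gamma marginals parametrized by mean/SD/skewness, coupled
   by a Gaussian copula whose correlation matrix is positive definite by
   construction.

3. **Observation.** Two-channel cytometry: channel gains α₁, α₂,
   imperfect quenching with efficiency η, multiplicative photomultiplier
   noise (constant CV), and empirical autofluorescence pairs resampled
   jointly from an unstained control.

Inference is two-tier, matching standard practice for such assays:

* `fit_gmfi()` — maximum-likelihood calibration of the homogeneous model to
  geometric-mean-fluorescence (GMFI) series, with observed-Fisher-information
  confidence intervals (`coef`, `confint`, `vcov`, `predict`, `summary`).
* `abc_smc()` / `abc_mcmc()` — distribution-matching approximate Bayesian
  computation for the heterogeneous model: a weighted sum of two-sample
  Anderson–Darling distances over every (time, condition, channel) marginal
  plus between-channel correlation discrepancies, a sequential Monte Carlo
  pilot to set the tolerance, and tuned ABC-MCMC chains with ESS/R-hat
  diagnostics.
* `internal_fraction_distribution()`, `surface_fraction_distribution()`,
  `between_time_dependence()`, `conditional_posterior()` — posterior
  prediction of per-cell quantities cytometry cannot measure.

`simulate_dataset()` generates complete synthetic assays with known ground
truth (1000 cells per time and condition by default, times spanning 0–120
min), so the whole pipeline is testable without any data download.

## Worked example

```r
library(flowintern)

# homogeneous-model rates (per minute) and channel gain
k  <- kinetic_params(lam = 0.106, beta = 0.047, p = 0.068)

# synthetic GMFI series at those rates, ~2% measurement noise
series <- simulate_gmfi_series(k, alpha1 = 7840, E_Q = 100, eta = 0.94,
                               sigma = 100, seed = 1)
fit <- fit_gmfi(series, E_Q = 100, eta = 0.94, seed = 1)
fit
#> Homogeneous internalization model (maximum likelihood)
#>
#>   lam         0.1106  95% CI (0.1001, 0.1211)  min^-1
#>   beta       0.04997  95% CI (0.04299, 0.05695)  min^-1
#>   p          0.06646  95% CI (0.05464, 0.07828)  -
#>   alpha1        7673  95% CI (7154, 8193)  fluor. units
#>
#>   equilibrium surface fraction S(0) = 0.311
#>   GMFI error SD sigma = 103.2; log-likelihood -82.279
```

The fitted rates say receptors internalize about twice as fast as they
recycle, so at equilibrium roughly a third of them sit on the surface
(S(0) ≈ 0.31 at the generating values); about 7% of internalized antibody
disassociates per recycling event, which is what makes total fluorescence
keep rising over two hours. All four generating values sit inside their 95%
intervals.

For the heterogeneous tier on a synthetic dataset with known truth:

```r
pp  <- population_params(mu_R = -0.125, sigma_R = 0.5,
                         mu_lam = 0.106, sigma_lam = 0.02, omega_lam = 0,
                         mu_beta = 0.047, sigma_beta = 0.012, omega_beta = 0,
                         rho_Rlam = -0.2, rho_lambeta = 0.3,
                         rho_tilde_Rbeta = -0.3, p = 0.068)
mp  <- measurement_params(alpha1 = 7840, alpha2 = 5000, eta = 0.94,
                          sigma1 = 0.1, sigma2 = 0.1)
obs <- simulate_dataset(pp, mp, study_design(), seed = 11)

prior <- abc_prior(max(gmfi_series(obs)$gmfi),
                   fixed = as_theta(pp)[-c(3, 6, 12)])  # reduced problem
cfg   <- discrepancy_config(n_sim = 1000)
sim   <- make_simulator(obs, prior, eta = 0.94, cfg)
cfg   <- calibrate_weights(obs, sim, prior, cfg, seed = 2)
smc   <- abc_smc(obs, sim, prior, cfg, n_particles = 200, seed = 3)
chain <- abc_mcmc(obs, sim, prior, smc$epsilon, smc$theta_min,
                  proposal_cov = cov(smc$particles), cfg = cfg,
                  n_chains = 4, n_steps = 3000, thin = 10, seed = 4)
summary(chain)   # marginal quantiles, ESS, R-hat per free parameter
```

`run_pipeline()` chains all stages (simulate → fit-gmfi → calibrate-weights
→ abc-smc → abc-mcmc → best-fit → predict) from a single config list/YAML
with per-stage artifacts and manifests.

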