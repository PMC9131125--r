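# shared fixtures: parameter sets and small synthetic datasets built in code

# homogeneous-model reference estimates (rates in min^-1)
ref_kinetics <- function() kinetic_params(lam = 0.106, beta = 0.047, p = 0.068)
ref_alpha1 <- 7840

# a moderately heterogeneous population used across tests
ref_population <- function(...) {
  args <- list(mu_R = -0.125, sigma_R = 0.5,
               mu_lam = 0.106, sigma_lam = 0.02, omega_lam = 0,
               mu_beta = 0.047, sigma_beta = 0.012, omega_beta = 0,
               rho_Rlam = -0.2, rho_lambeta = 0.3, rho_tilde_Rbeta = -0.3,
               p = 0.068)
  args[names(list(...))] <- list(...)
  do.call(population_params, args)
}

ref_measurement <- function(...) {
  args <- list(alpha1 = 7840, alpha2 = 5000, eta = 0.94,
               sigma1 = 0.1, sigma2 = 0.1)
  args[names(list(...))] <- list(...)
  do.call(measurement_params, args)
}

# a homogeneous, noise-free population (degenerate marginals)
homogeneous_population <- function(p = 0.068) {
  population_params(mu_R = 0, sigma_R = 0,
                    mu_lam = 0.106, sigma_lam = 0, omega_lam = 0,
                    mu_beta = 0.047, sigma_beta = 0, omega_beta = 0,
                    p = p)
}

small_design <- function(n = 200) {
  study_design(times = c(0, 10, 30, 120), n_per_sample = n,
               n_autofluorescence = 200)
}

# layout of the full ABC parameter vector
.abc_names <- function() flowintern:::.theta_names

# midpoint of a prior box (a deliberately poor parameter guess)
.prior_mid <- function(prior) (prior$lower + prior$upper) / 2

# brute-force two-sample Anderson-Darling oracle: direct evaluation of the
# rank formula (version over distinct pooled values), independent of the
# package's vectorized implementation
ad_bruteforce <- function(x, y) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  pooled <- sort(c(x, y))
  zstar <- unique(pooled)
  A2 <- 0
  for (j in seq_along(zstar)) {
    lj <- sum(pooled == zstar[j])
    Bj <- sum(pooled <= zstar[j])
    if (Bj >= N) next
    for (i in 1:2) {
      smp <- if (i == 1) x else y
      ni <- if (i == 1) n1 else n2
      Mij <- sum(smp <= zstar[j])
      A2 <- A2 + (1 / ni) * lj * (N * Mij - Bj * ni)^2 / (N * Bj * (N - Bj))
    }
  }
  H <- 1 / n1 + 1 / n2
  h <- sum(1 / seq_len(N - 1))
  g <- 0
  for (i in seq_len(N - 2)) {
    for (j in (i + 1):(N - 1)) g <- g + 1 / ((N - i) * j)
  }
  k <- 2
  a <- (4 * g - 6) * (k - 1) + (10 - 6 * g) * H
  b <- (2 * g - 4) * k^2 + 8 * h * k + (2 * g - 14 * h - 4) * H - 8 * h + 4 * g - 6
  cc <- (6 * h + 2 * g - 2) * k^2 + (4 * h - 4 * g + 6) * k + (2 * h - 6) * H + 4 * h
  d <- (2 * h + 6) * k^2 - 4 * h * k
  var_A2 <- (a * N^3 + b * N^2 + cc * N + d) / ((N - 1) * (N - 2) * (N - 3))
  (A2 - (k - 1)) / sqrt(var_A2)
}
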