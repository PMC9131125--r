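theta_ref <- function(...) {
  th <- c(as_theta(ref_population()), alpha1 = 7840, alpha2 = 5000,
          sigma1 = 0.1, sigma2 = 0.1)
  repl <- list(...)
  th[names(repl)] <- unlist(repl)
  th
}

# minimal hand-built chain for bookkeeping tests
toy_chain <- function(samples) {
  nms <- setdiff(names(samples), c("chain", "step", "d"))
  structure(list(samples = samples,
                 ess = stats::setNames(rep(nrow(samples), length(nms)), nms),
                 rhat = stats::setNames(rep(1, length(nms)), nms),
                 epsilon = Inf, thin = 1, acceptance_rate = 1),
            class = "abc_chain")
}

test_that("internal fraction starts at zero and collapses in the homogeneous limit", {
  th <- c(as_theta(homogeneous_population()), alpha1 = 7840, alpha2 = 5000,
          sigma1 = 0, sigma2 = 0)
  out <- internal_fraction_distribution(th, times = c(1e-9, 10, 60),
                                        n_cells = 200, seed = 61)
  expect_lt(max(out$fractions[, 1]), 1e-8)
  # zero heterogeneity: point mass at the homogeneous model's I/A
  tr <- solve_kinetics(ref_kinetics(), c(10, 60))
  expect_equal(unique(round(out$fractions[, 2], 12)),
               round(tr$I[1] / tr$A[1], 12))
  expect_equal(out$gmfi_ratio[["60"]], tr$I[2] / tr$A[2], tolerance = 1e-10)
})

test_that("GMFI-ratio scalar lies inside the per-cell fraction support", {
  th <- theta_ref()
  out <- internal_fraction_distribution(th, times = c(10, 60, 120),
                                        n_cells = 5000, seed = 62)
  for (j in 1:3) {
    expect_gt(out$gmfi_ratio[[j]], min(out$fractions[, j]))
    expect_lt(out$gmfi_ratio[[j]], max(out$fractions[, j]))
  }
})

test_that("surface fraction distribution reflects the rate distributions", {
  # degenerate rates: point mass at beta/(lam+beta) = 0.31
  th_hom <- c(as_theta(homogeneous_population()), alpha1 = 7840,
              alpha2 = 5000, sigma1 = 0, sigma2 = 0)
  s <- surface_fraction_distribution(th_hom, n_cells = 100, seed = 63)
  expect_equal(unique(round(s$S0, 6)), round(0.047 / 0.153, 6))
  expect_equal(round(s$S0[1], 2), 0.31)

  # recycling mass near zero puts surface-fraction density near zero
  th_low <- theta_ref(mu_beta = 0.01, sigma_beta = 0.01)
  s2 <- surface_fraction_distribution(th_low, n_cells = 20000, seed = 64)
  expect_gt(mean(s2$S0 < 0.05), 0.02)

  # negative receptor/recycling dependence propagates to (R, S0)
  th_neg <- theta_ref(rho_Rlam = 0, rho_lambeta = 0, rho_tilde_Rbeta = -0.6)
  s3 <- surface_fraction_distribution(th_neg, n_cells = 1e5, seed = 65)
  expect_lt(cor(s3$R, s3$S0, method = "spearman"), 0)
})

test_that("between-time dependence is deterministic per cell and degenerates correctly", {
  # heterogeneity only in R: both signals proportional to R, rho = 1
  th_R <- c(as_theta(ref_population(sigma_lam = 0, sigma_beta = 0,
                                    rho_Rlam = 0, rho_lambeta = 0,
                                    rho_tilde_Rbeta = 0)),
            alpha1 = 7840, alpha2 = 5000, sigma1 = 0, sigma2 = 0)
  bt <- between_time_dependence(th_R, eta = 0.94, 10, 120, n_cells = 500,
                                seed = 66)
  expect_equal(bt$copula_rho, 1, tolerance = 1e-9)

  # zero heterogeneity entirely: correlation undefined, flagged not crashed
  th_hom <- c(as_theta(homogeneous_population()), alpha1 = 7840,
              alpha2 = 5000, sigma1 = 0, sigma2 = 0)
  bt0 <- between_time_dependence(th_hom, 0.94, 10, 120, n_cells = 50,
                                 seed = 67)
  expect_true(is.na(bt0$copula_rho))

  # stability across seeds at a heterogeneous parameter set
  th <- theta_ref()
  r1 <- between_time_dependence(th, 0.94, 10, 120, 1000, seed = 68)$copula_rho
  r2 <- between_time_dependence(th, 0.94, 10, 120, 1000, seed = 69)$copula_rho
  expect_lt(abs(r1 - r2), 0.03)
  expect_error(between_time_dependence(th, 0.94, 120, 10), "before")
})

test_that("posterior conditioning and fractions do exact bookkeeping", {
  samples <- data.frame(chain = 1, step = 1:4,
                        mu_beta = c(0.01, 0.05, 0.08, 0.2),
                        sigma_beta = c(0.05, 0.01, 0.02, 0.3),
                        d = 0)
  ch <- toy_chain(samples)
  expect_equal(posterior_fraction(ch, function(th) th[["mu_beta"]] > 0.04),
               0.75)
  expect_equal(posterior_fraction(ch, function(th) FALSE), 0)
  cond <- conditional_posterior(ch, function(th) th[["mu_beta"]] > 0.04)
  expect_equal(nrow(cond$samples), 3)
  expect_equal(attr(cond, "retained_fraction"), 0.75)
  all_in <- conditional_posterior(ch, function(th) TRUE)
  expect_equal(all_in$samples, ch$samples)
  expect_error(conditional_posterior(ch, function(th) FALSE), "every")
})

test_that("conditioning on a simulation-based dependence predicate filters the posterior consistently", {
  # posterior stand-in: a spread of sigma_R values, which directly drive the
  # between-time copula correlation (shared receptor-count factor)
  n <- 16
  samples <- data.frame(chain = 1, step = 1:n,
                        sigma_R = seq(0.02, 0.9, length.out = n), d = 0)
  full <- theta_ref()
  rho_of <- function(th) {
    t2 <- full
    t2["sigma_R"] <- th[["sigma_R"]]
    between_time_dependence(t2, 0.94, 10, 120, n_cells = 400,
                            seed = 71)$copula_rho
  }
  ch <- toy_chain(samples)
  rhos <- sapply(seq_len(n), function(i) rho_of(samples[i, ]))
  thr <- median(rhos)
  cond <- conditional_posterior(ch, function(th) rho_of(th) >= thr)
  # retained set matches direct evaluation of the predicate, and conditioning
  # reshapes the marginal toward high-dependence configurations
  expect_equal(cond$samples$sigma_R, samples$sigma_R[rhos >= thr])
  expect_equal(attr(cond, "retained_fraction"), mean(rhos >= thr))
  expect_gt(min(sapply(seq_len(nrow(cond$samples)),
                       function(i) rho_of(cond$samples[i, ]))), thr - 1e-12)
})

test_that("predictive bands are well-formed and widen with posterior spread", {
  set.seed(72)
  narrow <- data.frame(chain = 1, step = 1:20,
                       mu_beta = rnorm(20, 0.047, 0.001), d = 0)
  wide <- narrow
  wide$mu_beta <- rnorm(20, 0.047, 0.02)
  full <- theta_ref()
  sample_fn <- function(th) {
    t2 <- full
    t2["mu_beta"] <- th[["mu_beta"]]
    surface_fraction_distribution(t2, n_cells = 400)$S0
  }
  grid <- seq(0, 1, length.out = 64)
  bn <- predictive_band(toy_chain(narrow), c(mu_beta = 0.047), sample_fn,
                        grid = grid, n_resample = 20, seed = 73)
  bw <- predictive_band(toy_chain(wide), c(mu_beta = 0.047), sample_fn,
                        grid = grid, n_resample = 20, seed = 74)
  expect_true(all(bn$band_lo <= bn$band_hi))
  expect_true(all(bn$density_best >= 0))
  expect_gt(mean(bw$band_hi - bw$band_lo), mean(bn$band_hi - bn$band_lo))
})
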