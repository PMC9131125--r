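#' Two-sample Anderson-Darling distance
#'
#' The standardized two-sample Anderson-Darling statistic of Scholz and
#' Stephens: the rank-based k-sample statistic \eqn{A^2_{kN}} (tie-adjusted,
#' evaluated over the distinct pooled values) centred at its null mean
#' \eqn{k - 1} and scaled by the exact null standard deviation
#' \eqn{\sigma_N}. Symmetric in its arguments; larger values indicate greater
#' separation between the empirical distributions.
#'
#' @param x,y Non-empty numeric samples.
#' @return The standardized statistic (a scalar; can be negative for samples
#'   closer than the null expectation).
#' @examples
#' ad_distance(rnorm(100), rnorm(100))
#' @export
ad_distance <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop("both samples must be non-empty")
  N <- n1 + n2
  pooled <- c(x, y)
  ord <- order(pooled)
  from_x <- c(rep(1, n1), rep(0, n2))[ord]
  z <- pooled[ord]
  # collapse to distinct values with multiplicities
  new_val <- c(TRUE, z[-1] != z[-N])
  grp <- cumsum(new_val)
  l <- tabulate(grp)                      # multiplicity of each distinct value
  Mx <- cumsum(from_x)[cumsum(l)]         # obs from x <= each distinct value
  B <- cumsum(l)                          # pooled obs <= each distinct value
  j <- which(B < N)
  # two-sample simplification: the y-sample term is proportional to the x term
  num <- (N * Mx[j] - B[j] * n1)^2
  A2 <- (1 / n1 + 1 / n2) * sum(l[j] * num / (N * B[j] * (N - B[j])))
  # exact null variance (k = 2)
  k <- 2
  H <- 1 / n1 + 1 / n2
  i_seq <- seq_len(N - 1)
  h <- sum(1 / i_seq)
  # g = sum_{i=1}^{N-2} (h_{N-1} - h_i) / (N - i), via cumulative sums
  if (N > 2) {
    hcum <- cumsum(1 / i_seq)             # h_i for i = 1..N-1
    i2 <- seq_len(N - 2)
    g <- sum((hcum[N - 1] - hcum[i2]) / (N - i2))
  } else {
    g <- 0
  }
  a <- (4 * g - 6) * (k - 1) + (10 - 6 * g) * H
  b <- (2 * g - 4) * k^2 + 8 * h * k +
    (2 * g - 14 * h - 4) * H - 8 * h + 4 * g - 6
  cc <- (6 * h + 2 * g - 2) * k^2 + (4 * h - 4 * g + 6) * k +
    (2 * h - 6) * H + 4 * h
  d <- (2 * h + 6) * k^2 - 4 * h * k
  var_A2 <- (a * N^3 + b * N^2 + cc * N + d) /
    ((N - 1) * (N - 2) * (N - 3))
  (A2 - (k - 1)) / sqrt(var_A2)
}

#' Discrepancy configuration
#'
#' Settings of the distribution-matching discrepancy: per-statistic weights,
#' the correlation estimator scale, and the simulated sample size.
#'
#' @param w_ad Weight of each univariate Anderson-Darling term (> 0).
#' @param w_corr Weight of each between-channel correlation term (> 0);
#'   typically set by [calibrate_weights()] so the two contributions are
#'   similar in magnitude.
#' @param corr_scale `"log"` (default): Pearson correlation of log-shifted
#'   signals `log(v - min(v) + 1)`, robust to the heavy right tail; or
#'   `"raw"`: Pearson correlation of the raw signals.
#' @param n_sim Cells per simulated (time, condition) sample.
#' @return An object of class `"discrepancy_config"`.
#' @export
discrepancy_config <- function(w_ad = 1, w_corr = 1,
                               corr_scale = c("log", "raw"), n_sim = 1000) {
  corr_scale <- match.arg(corr_scale)
  if (w_ad <= 0 || w_corr <= 0) stop("weights must be positive")
  structure(list(w_ad = w_ad, w_corr = w_corr, corr_scale = corr_scale,
                 n_sim = n_sim), class = "discrepancy_config")
}

.channel_cor <- function(Q, U, scale) {
  if (scale == "log") {
    Q <- log(Q - min(Q) + 1)
    U <- log(U - min(U) + 1)
  }
  stats::cor(Q, U)
}

## internal per-(time, condition) sample list: Q, U, r
.as_samples <- function(data, scale) {
  if (inherits(data, "ship_dataset")) data <- data$snapshots
  if (is.data.frame(data)) {
    key <- paste(data$time_min, data$condition, sep = "|")
    split_idx <- split(seq_len(nrow(data)), key)
    lapply(split_idx, function(i) {
      Q <- data$Q[i]; U <- data$U[i]
      list(Q = Q, U = U, r = .channel_cor(Q, U, scale))
    })
  } else {
    data  # already in internal form
  }
}

#' Distribution-matching discrepancy between two snapshot datasets
#'
#' The weighted discrepancy used for ABC: for every (time, condition) sample,
#' the standardized two-sample Anderson-Darling distance between observed and
#' simulated marginals of each fluorescence channel, plus the absolute
#' difference of the between-channel correlations, summed with weights
#' `w_ad` and `w_corr`.
#'
#' @param obs,sim Two datasets ([ship_dataset()] or bare snapshot data frames)
#'   sharing the same (time, condition) structure.
#' @param cfg A [discrepancy_config()].
#' @return The total discrepancy, with attribute `components` (named vector
#'   with the unweighted `ad` and `corr` totals).
#' @export
discrepancy <- function(obs, sim, cfg = discrepancy_config()) {
  so <- .as_samples(obs, cfg$corr_scale)
  ss <- .as_samples(sim, cfg$corr_scale)
  if (!setequal(names(so), names(ss))) {
    stop("observed and simulated datasets have different (time, condition) structure")
  }
  ad_tot <- 0
  corr_tot <- 0
  for (nm in names(so)) {
    o <- so[[nm]]; s <- ss[[nm]]
    ad_tot <- ad_tot + ad_distance(o$Q, s$Q) + ad_distance(o$U, s$U)
    corr_tot <- corr_tot + abs(o$r - s$r)
  }
  structure(cfg$w_ad * ad_tot + cfg$w_corr * corr_tot,
            components = c(ad = ad_tot, corr = corr_tot))
}

## full ABC parameter vector layout
.theta_names <- c("mu_R", "sigma_R", "mu_lam", "sigma_lam", "omega_lam",
                  "mu_beta", "sigma_beta", "omega_beta",
                  "rho_Rlam", "rho_lambeta", "rho_tilde_Rbeta", "p",
                  "alpha1", "alpha2", "sigma1", "sigma2")

#' Uniform prior box over the ABC parameter vector
#'
#' Independent uniform priors for the 16-component heterogeneous-model
#' parameter vector. Defaults are artifact choices reflecting physical
#' constraints (bounded correlations; positive rates, SDs and scales) and
#' realistic magnitudes relative to the data; every bound can be overridden.
#' A reduced problem is obtained by passing `fixed`, a named vector of
#' components to pin (those components are removed from the free vector).
#'
#' @param gmfi_max Largest observed GMFI, used to scale the channel-gain
#'   bounds.
#' @param lower,upper Optional named overrides of individual bounds.
#' @param fixed Optional named numeric vector of pinned components.
#' @return An object of class `"abc_prior"`: list with `lower`, `upper`
#'   (free components) and `fixed`.
#' @export
abc_prior <- function(gmfi_max, lower = NULL, upper = NULL, fixed = NULL) {
  lo <- c(mu_R = -2, sigma_R = 1e-3, mu_lam = 1e-3, sigma_lam = 1e-3,
          omega_lam = -2, mu_beta = 1e-3, sigma_beta = 1e-3, omega_beta = -2,
          rho_Rlam = -0.99, rho_lambeta = -0.99, rho_tilde_Rbeta = -0.99,
          p = 0, alpha1 = 1e-2 * gmfi_max, alpha2 = 1e-2 * gmfi_max,
          sigma1 = 0, sigma2 = 0)
  hi <- c(mu_R = 0, sigma_R = 1, mu_lam = 0.5, sigma_lam = 0.3,
          omega_lam = 2, mu_beta = 0.5, sigma_beta = 0.3, omega_beta = 2,
          rho_Rlam = 0.99, rho_lambeta = 0.99, rho_tilde_Rbeta = 0.99,
          p = 0.2, alpha1 = 5 * gmfi_max, alpha2 = 5 * gmfi_max,
          sigma1 = 0.5, sigma2 = 0.5)
  if (!is.null(lower)) lo[names(lower)] <- lower
  if (!is.null(upper)) hi[names(upper)] <- upper
  if (!is.null(fixed)) {
    bad <- setdiff(names(fixed), .theta_names)
    if (length(bad)) stop("unknown fixed parameters: ", paste(bad, collapse = ", "))
    lo <- lo[setdiff(names(lo), names(fixed))]
    hi <- hi[setdiff(names(hi), names(fixed))]
  }
  if (any(hi <= lo)) stop("upper bounds must exceed lower bounds")
  structure(list(lower = lo, upper = hi, fixed = fixed), class = "abc_prior")
}

.prior_sample <- function(prior, n) {
  d <- length(prior$lower)
  u <- matrix(stats::runif(n * d), n, d)
  th <- sweep(u, 2, prior$upper - prior$lower, `*`)
  th <- sweep(th, 2, prior$lower, `+`)
  colnames(th) <- names(prior$lower)
  th
}

.in_prior <- function(theta, prior) {
  all(theta >= prior$lower & theta <= prior$upper)
}

.full_theta <- function(theta, prior) {
  full <- c(theta, prior$fixed)
  full[.theta_names]
}

#' Forward simulator for ABC
#'
#' Builds a closure simulating a synthetic snapshot dataset matching the
#' structure of the observed one at a given free-parameter vector:
#' heterogeneous cells are sampled per (time, condition) sample, the
#' compartment model is solved, and cells are observed through the cytometry
#' noise model using the observed autofluorescence control as the empirical
#' background. The quench efficiency is fixed (pre-estimated).
#'
#' @param obs Observed [ship_dataset()].
#' @param prior An [abc_prior()] (supplies pinned components of reduced
#'   problems).
#' @param eta Fixed quench efficiency.
#' @param cfg A [discrepancy_config()] (supplies `n_sim` and the correlation
#'   scale).
#' @return A function `f(theta)` returning a simulated dataset in the internal
#'   per-sample form accepted by [discrepancy()].
#' @export
make_simulator <- function(obs, prior, eta, cfg = discrepancy_config()) {
  af <- obs$autofluorescence
  n_af <- if (is.null(af)) 0L else nrow(af)
  grid <- unique(obs$snapshots[c("time_min", "condition")])
  keys <- paste(grid$time_min, grid$condition, sep = "|")
  n_sim <- cfg$n_sim
  scale <- cfg$corr_scale
  function(theta) {
    full <- .full_theta(theta, prior)
    pp <- theta_to_population(full)
    mp <- measurement_params(full[["alpha1"]], full[["alpha2"]], eta,
                             full[["sigma1"]], full[["sigma2"]])
    out <- vector("list", nrow(grid))
    names(out) <- keys
    for (i in seq_len(nrow(grid))) {
      cells <- sample_cells(pp, n_sim)
      tr <- cell_trajectories(cells, pp$p, grid$time_min[i])
      o <- observe_cells(cells, tr$A[, 1], tr$I[, 1], tr$S[, 1], mp,
                         condition = grid$condition[i], af = af)
      out[[i]] <- list(Q = o$Q, U = o$U,
                       r = .channel_cor(o$Q, o$U, scale))
    }
    out
  }
}

#' Calibrate the discrepancy weights on a pilot of prior draws
#'
#' Simulates `n_pilot` datasets at parameters drawn from the prior and sets
#' the correlation weight so the median total correlation contribution equals
#' the median total Anderson-Darling contribution (`w_ad` stays 1).
#'
#' @param obs Observed dataset.
#' @param simulator Simulator from [make_simulator()].
#' @param prior An [abc_prior()].
#' @param cfg Starting [discrepancy_config()].
#' @param n_pilot Number of pilot draws (>= 10).
#' @param seed Optional integer seed.
#' @return A [discrepancy_config()] with calibrated `w_corr`.
#' @export
calibrate_weights <- function(obs, simulator, prior,
                              cfg = discrepancy_config(), n_pilot = 50,
                              seed = NULL) {
  if (n_pilot < 10) stop("'n_pilot' must be at least 10")
  obs <- .as_samples(obs, cfg$corr_scale)
  if (!is.null(seed)) set.seed(seed)
  thetas <- .prior_sample(prior, n_pilot)
  comp <- t(vapply(seq_len(n_pilot), function(i) {
    d <- tryCatch(discrepancy(obs, simulator(thetas[i, ]), cfg),
                  error = function(e) structure(NA_real_,
                    components = c(ad = NA_real_, corr = NA_real_)))
    attr(d, "components")
  }, c(ad = 0, corr = 0)))
  med_ad <- stats::median(comp[, "ad"], na.rm = TRUE)
  med_corr <- stats::median(comp[, "corr"], na.rm = TRUE)
  w_corr <- if (med_corr > 0) med_ad / med_corr else 1
  discrepancy_config(w_ad = cfg$w_ad, w_corr = w_corr,
                     corr_scale = cfg$corr_scale, n_sim = cfg$n_sim)
}

#' ABC sequential Monte Carlo pilot
#'
#' Adaptive ABC-SMC with a discrepancy-quantile threshold schedule, used to
#' choose the ABC tolerance and to locate the global discrepancy minimum
#' before MCMC. Each generation keeps the best `target_quantile` fraction of
#' particles (setting the next tolerance at that quantile), resamples to the
#' full population, and moves each resampled particle by a Metropolis step
#' with a Gaussian kernel whose covariance is twice the empirical particle
#' covariance (proposals outside the prior or with discrepancy above the
#' tolerance are rejected). The algorithm stops when the move acceptance rate
#' falls below `min_accept` or after `max_generations`.
#'
#' @param obs Observed dataset.
#' @param simulator Simulator from [make_simulator()].
#' @param prior An [abc_prior()].
#' @param cfg A [discrepancy_config()].
#' @param n_particles Number of particles (>= 50).
#' @param target_quantile Fraction of particles kept per generation.
#' @param max_generations Upper bound on generations.
#' @param min_accept Move-acceptance floor that stops the schedule (applied
#'   to a two-generation moving average, since per-generation rates are
#'   noisy).
#' @param min_generations Generations to run before the floor applies.
#' @param seed Optional integer seed.
#' @return A list of class `"abc_smc"`: `particles` (matrix), `d`
#'   (discrepancies), `epsilon`, `theta_min` (particle with lowest average
#'   discrepancy over `n_reps_min` re-simulations), `history` (per-generation
#'   tolerance and acceptance).
#' @param n_reps_min Re-simulations per candidate when picking `theta_min`.
#' @export
abc_smc <- function(obs, simulator, prior, cfg = discrepancy_config(),
                    n_particles = 200, target_quantile = 0.5,
                    max_generations = 12, min_accept = 0.015,
                    min_generations = 5, n_reps_min = 5, seed = NULL) {
  if (n_particles < 50) stop("'n_particles' must be at least 50")
  obs <- .as_samples(obs, cfg$corr_scale)
  if (!is.null(seed)) set.seed(seed)
  d_names <- names(prior$lower)
  th <- .prior_sample(prior, n_particles)
  d <- vapply(seq_len(n_particles),
              function(i) as.numeric(discrepancy(obs, simulator(th[i, ]), cfg)),
              0)
  history <- data.frame(generation = integer(), epsilon = double(),
                        acceptance = double())
  eps <- max(d)
  degenerate_prior <- all(prior$upper - prior$lower < 1e-8)
  for (gen in seq_len(max_generations)) {
    eps <- as.numeric(stats::quantile(d, target_quantile))
    keep <- which(d <= eps)
    idx <- sample(keep, n_particles, replace = TRUE)
    th_new <- th[idx, , drop = FALSE]
    d_new <- d[idx]
    if (degenerate_prior) { th <- th_new; d <- d_new; break }
    Sigma <- 2 * stats::cov(th[keep, , drop = FALSE])
    # regularize in case of near-degenerate particle clouds
    diag(Sigma) <- diag(Sigma) + 1e-12 * (prior$upper - prior$lower)^2
    L <- tryCatch(chol(Sigma), error = function(e) NULL)
    acc <- 0L
    for (i in seq_len(n_particles)) {
      prop <- th_new[i, ] + drop(stats::rnorm(length(d_names)) %*% L)
      if (!.in_prior(prop, prior)) next
      dp <- as.numeric(discrepancy(obs, simulator(prop), cfg))
      if (dp <= eps) {
        th_new[i, ] <- prop
        d_new[i] <- dp
        acc <- acc + 1L
      }
    }
    th <- th_new
    d <- d_new
    rate <- acc / n_particles
    history <- rbind(history,
                     data.frame(generation = gen, epsilon = eps,
                                acceptance = rate))
    if (length(unique(apply(th, 1, paste, collapse = ","))) < 10) {
      warning("SMC particle degeneracy: fewer than 10 unique particles; ",
              "stopping the tolerance schedule early")
      break
    }
    rate_ma <- mean(utils::tail(history$acceptance, 2))
    if (gen >= min_generations && rate_ma < min_accept) break
  }
  # best particle: lowest average discrepancy over fresh re-simulations
  n_top <- min(20L, n_particles)
  top <- order(d)[seq_len(n_top)]
  avg <- vapply(top, function(i) {
    mean(vapply(seq_len(n_reps_min), function(r)
      as.numeric(discrepancy(obs, simulator(th[i, ]), cfg)), 0))
  }, 0)
  theta_min <- th[top[which.min(avg)], ]
  structure(list(particles = th, d = d, epsilon = eps, theta_min = theta_min,
                 history = history), class = "abc_smc")
}

#' @export
print.abc_smc <- function(x, ...) {
  cat("ABC-SMC pilot:", nrow(x$particles), "particles,",
      nrow(x$history), "generations, final epsilon =",
      format(x$epsilon, digits = 4), "\n")
  invisible(x)
}

#' ABC Markov chain Monte Carlo
#'
#' Tuned random-walk ABC-MCMC targeting the approximate posterior
#' `p(theta | d(obs, sim(theta)) < epsilon)`: Gaussian proposals (covariance
#' typically from the SMC particle cloud, rescaled by `scale`) are accepted
#' iff they lie inside the uniform prior box and a fresh simulation at the
#' proposal has discrepancy below `epsilon`. Several independent chains are
#' run from `theta_init` (e.g. the SMC global minimum); every `thin`-th state
#' is retained with its discrepancy.
#'
#' @param obs Observed dataset.
#' @param simulator Simulator from [make_simulator()].
#' @param prior An [abc_prior()].
#' @param epsilon ABC tolerance (from [abc_smc()]).
#' @param theta_init Named start vector; a simulation at the start must meet
#'   `epsilon` within `init_retries` attempts.
#' @param proposal_cov Proposal covariance before scaling.
#' @param cfg A [discrepancy_config()].
#' @param n_chains Number of independent chains.
#' @param n_steps Steps per chain.
#' @param thin Retain every `thin`-th state.
#' @param scale Multiplier applied to `proposal_cov` (tune for acceptance in
#'   roughly 0.1-0.3).
#' @param init_retries Attempts to find an initial simulation under epsilon.
#' @param seed Optional integer seed.
#' @return An object of class `"abc_chain"`: `samples` (data frame with
#'   `chain`, `step`, one column per free parameter, and `d`),
#'   `acceptance_rate`, `epsilon`, `thin`, `ess`, `rhat`.
#' @export
abc_mcmc <- function(obs, simulator, prior, epsilon, theta_init,
                     proposal_cov, cfg = discrepancy_config(),
                     n_chains = 4, n_steps = 5000, thin = 20, scale = 1,
                     init_retries = 20, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  obs <- .as_samples(obs, cfg$corr_scale)
  d_names <- names(prior$lower)
  theta_init <- theta_init[d_names]
  Sigma <- scale * proposal_cov
  diag(Sigma) <- diag(Sigma) + 1e-12 * (prior$upper - prior$lower)^2
  L <- chol(Sigma)
  ok <- FALSE
  d0 <- Inf
  for (r in seq_len(init_retries)) {
    d0 <- as.numeric(discrepancy(obs, simulator(theta_init), cfg))
    if (d0 < epsilon) { ok <- TRUE; break }
  }
  if (!ok) {
    stop("abc_mcmc(): no simulation at 'theta_init' met epsilon after ",
         init_retries, " attempts (last d = ", format(d0, digits = 4), ")")
  }
  keep_every <- max(1L, as.integer(thin))
  all_samples <- list()
  n_acc <- 0L
  for (ch in seq_len(n_chains)) {
    th <- theta_init
    d_cur <- d0
    n_keep <- n_steps %/% keep_every
    kept <- matrix(NA_real_, n_keep, length(d_names) + 1)
    ki <- 0L
    for (s in seq_len(n_steps)) {
      prop <- th + drop(stats::rnorm(length(d_names)) %*% L)
      if (.in_prior(prop, prior) || is.infinite(epsilon)) {
        if (is.infinite(epsilon)) {
          if (.in_prior(prop, prior)) { th <- prop; d_cur <- NA_real_; n_acc <- n_acc + 1L }
        } else {
          dp <- as.numeric(discrepancy(obs, simulator(prop), cfg))
          if (dp < epsilon) {
            th <- prop
            d_cur <- dp
            n_acc <- n_acc + 1L
          }
        }
      }
      if (s %% keep_every == 0L) {
        ki <- ki + 1L
        kept[ki, ] <- c(th, d_cur)
      }
    }
    df <- as.data.frame(kept[seq_len(ki), , drop = FALSE])
    names(df) <- c(d_names, "d")
    df <- cbind(chain = ch, step = seq_len(ki) * keep_every, df)
    all_samples[[ch]] <- df
  }
  samples <- do.call(rbind, all_samples)
  diag_mat <- lapply(all_samples, function(s) as.matrix(s[d_names]))
  ess <- vapply(d_names, function(nm)
    sum(vapply(diag_mat, function(m) .ess(m[, nm]), 0)), 0)
  rhat <- vapply(d_names, function(nm)
    .rhat(lapply(diag_mat, function(m) m[, nm])), 0)
  structure(list(samples = samples,
                 acceptance_rate = n_acc / (n_chains * n_steps),
                 epsilon = epsilon, thin = keep_every,
                 ess = ess, rhat = rhat, prior = prior),
            class = "abc_chain")
}

## effective sample size via the initial positive-sequence autocorrelation sum
.ess <- function(x) {
  n <- length(x)
  if (n < 4 || stats::var(x) == 0) return(n)
  lag_max <- min(n - 1, 200L)
  rho <- stats::acf(x, lag.max = lag_max, plot = FALSE)$acf[-1]
  s <- 0
  for (i in seq_along(rho)) {
    if (rho[i] <= 0) break
    s <- s + rho[i]
  }
  n / (1 + 2 * s)
}

## split-chain potential scale reduction factor
.rhat <- function(chains) {
  halves <- unlist(lapply(chains, function(x) {
    m <- length(x) %/% 2
    list(x[seq_len(m)], x[m + seq_len(m)])
  }), recursive = FALSE)
  m <- length(halves)
  n <- length(halves[[1]])
  if (n < 2) return(NA_real_)
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, stats::var, 0)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' @export
print.abc_chain <- function(x, ...) {
  d_names <- names(x$ess)
  cat("ABC-MCMC posterior sample\n")
  cat(sprintf("  %d chains, %d retained samples (thin %d), epsilon = %s\n",
              length(unique(x$samples$chain)), nrow(x$samples), x$thin,
              format(x$epsilon, digits = 4)))
  cat(sprintf("  acceptance rate %.3f; min ESS %.0f; max R-hat %.3f\n",
              x$acceptance_rate, min(x$ess), max(x$rhat, na.rm = TRUE)))
  invisible(x)
}

#' @export
summary.abc_chain <- function(object, ...) {
  d_names <- names(object$ess)
  qs <- t(vapply(d_names, function(nm)
    stats::quantile(object$samples[[nm]], c(0.025, 0.25, 0.5, 0.75, 0.975)),
    numeric(5)))
  out <- data.frame(qs, ess = object$ess, rhat = object$rhat)
  names(out)[1:5] <- c("q2.5", "q25", "median", "q75", "q97.5")
  out
}

#' @export
as.data.frame.abc_chain <- function(x, ...) x$samples

#' Select the best-fitting parameter set from an ABC chain
#'
#' Evenly thins the chain to `n_candidates` parameter sets, estimates each
#' candidate's mean discrepancy over `n_reps` fresh simulations, and returns
#' the minimizer (ties broken by chain order).
#'
#' @param chain An `"abc_chain"`.
#' @param obs Observed dataset.
#' @param simulator Simulator from [make_simulator()].
#' @param cfg A [discrepancy_config()].
#' @param n_candidates Number of candidates after thinning.
#' @param n_reps Fresh simulations per candidate.
#' @param seed Optional integer seed.
#' @return Named numeric vector: the selected free-parameter values, with
#'   attribute `mean_d`.
#' @export
select_best_fit <- function(chain, obs, simulator, cfg = discrepancy_config(),
                            n_candidates = 400, n_reps = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  obs <- .as_samples(obs, cfg$corr_scale)
  d_names <- names(chain$ess)
  n <- nrow(chain$samples)
  if (n < n_candidates) n_candidates <- n
  idx <- unique(round(seq(1, n, length.out = n_candidates)))
  best_i <- NA_integer_
  best_d <- Inf
  for (i in idx) {
    th <- unlist(chain$samples[i, d_names, drop = FALSE])
    md <- mean(vapply(seq_len(n_reps), function(r)
      as.numeric(discrepancy(obs, simulator(th), cfg)), 0))
    if (md < best_d) { best_d <- md; best_i <- i }
  }
  structure(unlist(chain$samples[best_i, d_names, drop = FALSE]), mean_d = best_d)
}
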