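#' Study design for a synthetic internalization assay
#'
#' Defines the sampling layout of a synthetic flow-cytometry internalization
#' experiment: observation times, cells per (time, condition) sample, and the
#' size of the autofluorescence control. Defaults follow the study conditions:
#' 1000 cells per observation time per condition, observation times spanning
#' 0-120 minutes.
#'
#' @param times Observation times in minutes (non-empty, non-negative).
#' @param n_per_sample Cells per (time, condition) sample.
#' @param n_autofluorescence Cells in the autofluorescence control sample.
#' @return An object of class `"study_design"`.
#' @export
study_design <- function(times = c(0, 5, 10, 20, 30, 60, 120),
                         n_per_sample = 1000,
                         n_autofluorescence = 1000) {
  if (length(times) == 0 || any(times < 0)) {
    stop("'times' must be non-empty and non-negative")
  }
  if (n_per_sample < 1) stop("'n_per_sample' must be >= 1")
  structure(list(times = sort(times), n_per_sample = n_per_sample,
                 n_autofluorescence = n_autofluorescence),
            class = "study_design")
}

#' Autofluorescence background model
#'
#' A heavy-tailed, positively correlated bivariate log-normal emulating the
#' unstained-control background of a flow cytometer. Any user-supplied
#' two-column sample (`EQ`, `EU`) can replace draws from this model.
#'
#' @param median_Q,median_U Channel medians in fluorescence units.
#' @param cv_Q,cv_U Coefficients of variation of each channel.
#' @param rho Log-scale correlation between the channels.
#' @return A function `f(n)` returning a data frame of `n` (`EQ`, `EU`) pairs.
#' @export
af_lognormal_model <- function(median_Q = 100, median_U = 100,
                               cv_Q = 0.6, cv_U = 0.6, rho = 0.5) {
  s1 <- sqrt(log(1 + cv_Q^2))
  s2 <- sqrt(log(1 + cv_U^2))
  function(n) {
    z1 <- stats::rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
    data.frame(EQ = median_Q * exp(s1 * z1), EU = median_U * exp(s2 * z2))
  }
}

#' Generate a complete synthetic internalization-assay dataset
#'
#' Forward-composes the full generative model with known ground truth: for
#' each (time, condition) sample it draws an independent heterogeneous cell
#' population ([sample_cells()]), solves the compartment model per cell
#' ([cell_trajectories()]), and observes the cells through the cytometry noise
#' model ([observe_cells()]). An autofluorescence control sample and a 4C
#' quench-efficiency control (internalization frozen: compartments held at the
#' antibody-saturated equilibrium surface state, I = 0) are generated
#' alongside. The generating parameters and the per-cell latent properties of
#' every sample are stored in the returned dataset's `truth` slot.
#'
#' @param pp A [population_params()] object.
#' @param mp A [measurement_params()] object.
#' @param design A [study_design()].
#' @param af_model Function `f(n)` returning autofluorescence pairs, or `NULL`
#'   for a zero background. Default: [af_lognormal_model()].
#' @param seed Optional integer seed.
#' @return A [ship_dataset()] with ground truth attached.
#' @export
simulate_dataset <- function(pp, mp, design = study_design(),
                             af_model = af_lognormal_model(),
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  af <- if (is.null(af_model)) NULL else af_model(design$n_autofluorescence)
  snaps <- list()
  latents <- list()
  for (tm in design$times) {
    for (cond in c("unquenched", "quenched")) {
      cells <- sample_cells(pp, design$n_per_sample)
      tr <- cell_trajectories(cells, pp$p, tm)
      obs <- observe_cells(cells, tr$A[, 1], tr$I[, 1], tr$S[, 1], mp,
                           condition = cond, af = af)
      snaps[[length(snaps) + 1L]] <- data.frame(
        time_min = tm, condition = cond, Q = obs$Q, U = obs$U)
      latents[[paste(tm, cond, sep = "_")]] <- cells
    }
  }
  # 4C control: internalization inhibited, all antibody surface-bound at the
  # equilibrium surface fraction (A = S = S(0), I = 0)
  qc_cells <- sample_cells(pp, design$n_per_sample)
  S0 <- qc_cells$beta / (qc_cells$lam + qc_cells$beta)
  zero <- rep(0, nrow(qc_cells))
  qc_u <- observe_cells(qc_cells, S0, zero, S0, mp, "unquenched", af)
  qc_q <- observe_cells(qc_cells, S0, zero, S0, mp, "quenched", af)
  quench_control <- list(q_gmfi = as.numeric(gmfi(qc_q$Q)),
                         u_gmfi = as.numeric(gmfi(qc_u$Q)))
  truth <- list(
    population = unclass(pp),
    measurement = unclass(mp)[c("alpha1", "alpha2", "eta", "sigma1", "sigma2")],
    design = unclass(design),
    cells = latents
  )
  ship_dataset(do.call(rbind, snaps), af, quench_control = quench_control,
               truth = truth)
}

#' Homogeneous-model GMFI prediction
#'
#' Deterministic GMFI curves of the homogeneous (no cell-to-cell variability)
#' model: unquenched `alpha1 * A(t) + E_Q` and quenched
#' `alpha1 * [I(t) + (1 - eta) * S(t)] + E_Q`, where `A`, `I`, `S` solve the
#' compartment model at the population-level rates.
#'
#' @param k A [kinetic_params()] object.
#' @param alpha1 Q-channel scale.
#' @param E_Q Mean autofluorescence (GMFI units).
#' @param eta Quench efficiency.
#' @param times Observation times (minutes).
#' @return Data frame with columns `time_min`, `unquenched`, `quenched`.
#' @export
homogeneous_gmfi <- function(k, alpha1, E_Q, eta, times) {
  tr <- solve_kinetics(k, times)
  data.frame(
    time_min = times,
    unquenched = alpha1 * tr$A + E_Q,
    quenched = alpha1 * (tr$I + (1 - eta) * tr$S) + E_Q
  )
}

#' Generate a noisy homogeneous GMFI series
#'
#' The fixture for homogeneous-model fitting: the deterministic
#' [homogeneous_gmfi()] curves observed with independent additive
#' `Normal(0, sigma^2)` measurement errors per time point and condition.
#'
#' @param k A [kinetic_params()] object.
#' @param alpha1 Q-channel scale.
#' @param E_Q Mean autofluorescence.
#' @param eta Quench efficiency.
#' @param sigma GMFI measurement-error SD (fluorescence units).
#' @param times Observation times (minutes).
#' @param seed Optional integer seed.
#' @return Data frame with columns `time_min`, `condition`, `gmfi`.
#' @export
simulate_gmfi_series <- function(k, alpha1, E_Q, eta, sigma,
                                 times = c(0, 5, 10, 20, 30, 60, 120),
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mod <- homogeneous_gmfi(k, alpha1, E_Q, eta, times)
  data.frame(
    time_min = rep(times, 2),
    condition = rep(c("unquenched", "quenched"), each = length(times)),
    gmfi = c(mod$unquenched + stats::rnorm(length(times), 0, sigma),
             mod$quenched + stats::rnorm(length(times), 0, sigma))
  )
}
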