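#' Predicted distribution of the internalized fraction
#'
#' Simulates the heterogeneous model with all measurement noise removed and
#' returns the per-cell internalized fraction `I(t) / A(t)` at each requested
#' time, together with the scalar GMFI-ratio estimator
#' `Ifrac(t) = GMFI(I) / GMFI(A)` computed on the same noise-free per-cell
#' amounts (the population-level summary a homogeneous analysis would report).
#'
#' @param theta Full or free+fixed named parameter vector (the 12 population
#'   components are used; see [theta_to_population()]).
#' @param times Times in minutes (> 0; at t = 0 the fraction is identically
#'   0).
#' @param n_cells Cells to simulate.
#' @param seed Optional integer seed.
#' @return A list with `fractions` (an `n_cells` x `length(times)` matrix of
#'   per-cell `I/A`) and `gmfi_ratio` (named vector, one entry per time).
#' @export
internal_fraction_distribution <- function(theta, times, n_cells = 10000,
                                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pp <- theta_to_population(theta)
  cells <- sample_cells(pp, n_cells)
  tr <- cell_trajectories(cells, pp$p, times)
  frac <- tr$I / pmax(tr$A, .Machine$double.xmin)
  colnames(frac) <- as.character(times)
  # per-cell amounts scale with R in fluorescence space; GMFI ratio of
  # alpha1*I*R over alpha1*A*R reduces to GMFI(I*R)/GMFI(A*R)
  gr <- vapply(seq_along(times), function(j) {
    as.numeric(gmfi(tr$I[, j] * cells$R)) / as.numeric(gmfi(tr$A[, j] * cells$R))
  }, 0)
  names(gr) <- as.character(times)
  list(fractions = frac, gmfi_ratio = gr)
}

#' Predicted distribution of the equilibrium surface-receptor fraction
#'
#' Samples cells from the fitted population and returns the per-cell
#' equilibrium surface fraction `S(0) = beta / (lam + beta)` together with the
#' paired relative receptor count, enabling dependence summaries between
#' receptor abundance and surface localization.
#'
#' @param theta Named parameter vector (population components used).
#' @param n_cells Cells to simulate.
#' @param seed Optional integer seed.
#' @return Data frame with columns `S0` and `R`.
#' @export
surface_fraction_distribution <- function(theta, n_cells = 10000,
                                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pp <- theta_to_population(theta)
  cells <- sample_cells(pp, n_cells)
  data.frame(S0 = cells$beta / (cells$lam + cells$beta), R = cells$R)
}

#' Between-time dependence of the noise-free quenched signal
#'
#' Flow cytometry destroys cell identity between snapshots, so the joint
#' distribution of a cell's signal at two times is unobservable; the fitted
#' model predicts it. For a common set of simulated cells the noise-free
#' quenched Q-channel signal `alpha1 * [I(t) + (1 - eta) * S(t)] * R` is
#' computed at both times (deterministic given the cell's properties), and
#' the dependence is summarized by a Gaussian-copula correlation estimated
#' from normal-scores (van der Waerden) transformed ranks.
#'
#' @param theta Named parameter vector including `alpha1`.
#' @param eta Quench efficiency.
#' @param t_early,t_late Two times in minutes, `t_early < t_late`.
#' @param n_cells Cells to simulate.
#' @param seed Optional integer seed.
#' @return A list with `pairs` (data frame `Q_early`, `Q_late`) and
#'   `copula_rho` (scalar; `NA` with a message attribute when the population
#'   is degenerate and the correlation is undefined).
#' @export
between_time_dependence <- function(theta, eta, t_early = 10, t_late = 120,
                                    n_cells = 1000, seed = NULL) {
  if (t_early >= t_late) stop("'t_early' must be before 't_late'")
  if (!is.null(seed)) set.seed(seed)
  pp <- theta_to_population(theta)
  cells <- sample_cells(pp, n_cells)
  tr <- cell_trajectories(cells, pp$p, c(t_early, t_late))
  alpha1 <- theta[["alpha1"]]
  q <- alpha1 * (tr$I + (1 - eta) * tr$S) * cells$R
  pairs <- data.frame(Q_early = q[, 1], Q_late = q[, 2])
  if (stats::sd(pairs$Q_early) == 0 || stats::sd(pairs$Q_late) == 0) {
    rho <- structure(NA_real_, note = "degenerate population: correlation undefined")
  } else {
    ns <- function(v) stats::qnorm(rank(v, ties.method = "average") / (length(v) + 1))
    rho <- stats::cor(ns(pairs$Q_early), ns(pairs$Q_late))
  }
  list(pairs = pairs, copula_rho = rho)
}

#' Condition an ABC posterior on a predicate
#'
#' Filters a posterior chain to the samples satisfying a predicate (which may
#' itself require simulation, e.g. a between-time copula correlation
#' threshold), re-weighting downstream marginals to the conditioned subset.
#'
#' @param chain An `"abc_chain"`.
#' @param predicate Function taking a named parameter vector and returning
#'   `TRUE`/`FALSE`.
#' @return An `"abc_chain"` restricted to the satisfying samples, with
#'   attribute `retained_fraction`.
#' @export
conditional_posterior <- function(chain, predicate) {
  d_names <- names(chain$ess)
  keep <- vapply(seq_len(nrow(chain$samples)), function(i)
    isTRUE(predicate(unlist(chain$samples[i, d_names, drop = FALSE]))), NA)
  if (!any(keep)) stop("predicate excludes every posterior sample")
  out <- chain
  out$samples <- chain$samples[keep, , drop = FALSE]
  out$ess <- vapply(d_names, function(nm) .ess(out$samples[[nm]]), 0)
  attr(out, "retained_fraction") <- mean(keep)
  out
}

#' Fraction of posterior samples satisfying a predicate
#'
#' Convenience summary for posterior statements such as "the receptor count
#' and recycling rate are negatively correlated in X% of posterior samples".
#' For predicates on the derived copula entry `rho_Rbeta`, pass a predicate
#' taking the named vector: the implied value is available via
#' [copula_correlation()].
#'
#' @param chain An `"abc_chain"`.
#' @param predicate Function from a named parameter vector to logical.
#' @return Scalar fraction in \[0, 1\].
#' @examples
#' \dontrun{
#' posterior_fraction(chain, function(th)
#'   copula_correlation(th[["rho_Rlam"]], th[["rho_lambeta"]],
#'                      th[["rho_tilde_Rbeta"]])["R", "beta"] < 0)
#' }
#' @export
posterior_fraction <- function(chain, predicate) {
  d_names <- names(chain$ess)
  mean(vapply(seq_len(nrow(chain$samples)), function(i)
    isTRUE(predicate(unlist(chain$samples[i, d_names, drop = FALSE]))), NA))
}

#' Pointwise credible band for a predicted density
#'
#' Kernel-density band machinery for the predictive distributions: the
#' density of the predicted quantity is estimated (Gaussian kernel, Silverman
#' bandwidth) on a common grid at the best fit and at each of `n_resample`
#' posterior draws; the band is the pointwise 2.5%/97.5% envelope over the
#' resampled densities.
#'
#' @param chain An `"abc_chain"`.
#' @param best Named best-fit parameter vector (e.g. from
#'   [select_best_fit()]).
#' @param sample_fn Function from a named parameter vector to a numeric
#'   sample of the predicted quantity.
#' @param grid Grid on which densities are evaluated (default: range of the
#'   best-fit sample, 128 points).
#' @param n_resample Number of posterior resamples.
#' @param seed Optional integer seed.
#' @return Data frame with columns `grid`, `density_best`, `band_lo`,
#'   `band_hi`.
#' @export
predictive_band <- function(chain, best, sample_fn, grid = NULL,
                            n_resample = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d_names <- names(chain$ess)
  s_best <- sample_fn(best)
  if (is.null(grid)) {
    grid <- seq(min(s_best), max(s_best), length.out = 128)
  }
  dens_on <- function(v) {
    d <- stats::density(v, bw = "nrd0", from = min(grid), to = max(grid),
                        n = length(grid))
    stats::approx(d$x, d$y, xout = grid, rule = 2)$y
  }
  db <- dens_on(s_best)
  idx <- sample.int(nrow(chain$samples), n_resample, replace = TRUE)
  mat <- vapply(idx, function(i)
    dens_on(sample_fn(unlist(chain$samples[i, d_names, drop = FALSE]))), numeric(length(grid)))
  data.frame(grid = grid,
             density_best = db,
             band_lo = apply(mat, 1, stats::quantile, probs = 0.025),
             band_hi = apply(mat, 1, stats::quantile, probs = 0.975))
}
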