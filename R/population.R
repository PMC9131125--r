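#' Population-level heterogeneity parameters
#'
#' Describes cell-to-cell variability of the latent cell properties
#' \eqn{\xi_i = (R_i, \lambda_i, \beta_i)}: a shifted log-normal receptor
#' count with mean fixed at 1, shifted-Gamma internalization and recycling
#' rates parametrized by mean/SD/skewness, and a Gaussian copula coupling the
#' three marginals. The disassociation probability `p` is shared by all cells.
#'
#' The copula correlation between receptor count and recycling rate is not a
#' free parameter: it is derived from `rho_Rlam`, `rho_lambeta` and the
#' partial-correlation-like parameter `rho_tilde_Rbeta` so that the implied
#' 3x3 correlation matrix is always positive definite (see
#' [copula_correlation()]).
#'
#' @param mu_R,sigma_R Log-scale location and scale of the shifted log-normal
#'   receptor-count distribution (the shift is set so that `E(R) = 1`).
#' @param mu_lam,sigma_lam,omega_lam Mean (min^-1), SD (min^-1) and skewness
#'   (dimensionless) of the internalization rate.
#' @param mu_beta,sigma_beta,omega_beta Mean, SD and skewness of the recycling
#'   rate.
#' @param rho_Rlam,rho_lambeta,rho_tilde_Rbeta Copula dependence parameters,
#'   each in (-1, 1).
#' @param p Shared disassociation probability in \[0, 1\].
#'
#' @return An object of class `"population_params"` (named list).
#' @examples
#' pp <- population_params(mu_R = -0.25, sigma_R = 0.5,
#'                         mu_lam = 0.1, sigma_lam = 0.03, omega_lam = -0.5,
#'                         mu_beta = 0.05, sigma_beta = 0.015, omega_beta = -0.5,
#'                         rho_Rlam = -0.2, rho_lambeta = 0.3,
#'                         rho_tilde_Rbeta = -0.3, p = 0.05)
#' @export
population_params <- function(mu_R, sigma_R,
                              mu_lam, sigma_lam, omega_lam,
                              mu_beta, sigma_beta, omega_beta,
                              rho_Rlam = 0, rho_lambeta = 0,
                              rho_tilde_Rbeta = 0, p) {
  if (sigma_R < 0 || sigma_lam < 0 || sigma_beta < 0) {
    stop("standard deviations must be non-negative")
  }
  rho <- c(rho_Rlam, rho_lambeta, rho_tilde_Rbeta)
  if (any(rho <= -1) || any(rho >= 1)) {
    stop("copula parameters must lie in the open interval (-1, 1)")
  }
  if (p < 0 || p > 1) stop("'p' must lie in [0, 1]")
  structure(list(
    mu_R = mu_R, sigma_R = sigma_R,
    mu_lam = mu_lam, sigma_lam = sigma_lam, omega_lam = omega_lam,
    mu_beta = mu_beta, sigma_beta = sigma_beta, omega_beta = omega_beta,
    rho_Rlam = rho_Rlam, rho_lambeta = rho_lambeta,
    rho_tilde_Rbeta = rho_tilde_Rbeta, p = p
  ), class = "population_params")
}

#' @export
print.population_params <- function(x, ...) {
  cat("Population heterogeneity parameters\n")
  cat(sprintf("  R:      shifted log-normal(mu = %g, sigma = %g), E(R) = 1\n",
              x$mu_R, x$sigma_R))
  cat(sprintf("  lambda: shifted Gamma(mean = %g, sd = %g, skew = %g) /min\n",
              x$mu_lam, x$sigma_lam, x$omega_lam))
  cat(sprintf("  beta:   shifted Gamma(mean = %g, sd = %g, skew = %g) /min\n",
              x$mu_beta, x$sigma_beta, x$omega_beta))
  cat(sprintf("  copula: rho_Rlam = %g, rho_lambeta = %g, rho_tilde_Rbeta = %g\n",
              x$rho_Rlam, x$rho_lambeta, x$rho_tilde_Rbeta))
  cat(sprintf("  shared disassociation probability p = %g\n", x$p))
  invisible(x)
}

#' Quantile function of the moment-parametrized shifted Gamma distribution
#'
#' A Gamma distribution shifted and (for negative skewness) mirrored so that
#' its first three moments are exactly the requested mean, standard deviation
#' and skewness. With shape `k = 4 / omega^2` and scale `theta =
#' sigma * |omega| / 2`, the value is `mu + sign(omega) * (G - k * theta)`
#' where `G` is a Gamma(k, theta) quantile (of `u` for positive skew, of
#' `1 - u` for negative skew). As `|omega| -> 0` the shape diverges and the
#' distribution tends to Normal(mu, sigma^2); below `|omega| < 1e-3` the
#' normal quantile is used directly to avoid overflow in the shape parameter.
#'
#' @param u Probabilities in (0, 1).
#' @param mu Mean.
#' @param sigma Standard deviation (>= 0).
#' @param omega Skewness.
#' @return Quantiles of the shifted Gamma distribution.
#' @examples
#' qshifted_gamma(0.5, mu = 0, sigma = 1, omega = 1e-9)  # normal limit: 0
#' @export
qshifted_gamma <- function(u, mu, sigma, omega) {
  if (sigma < 0) stop("'sigma' must be non-negative")
  if (any(u <= 0) || any(u >= 1)) stop("'u' must lie in (0, 1)")
  if (sigma == 0) return(rep(mu, length(u)))
  if (abs(omega) < 1e-3) {
    return(stats::qnorm(u, mean = mu, sd = sigma))
  }
  k <- 4 / omega^2
  theta <- sigma * abs(omega) / 2
  us <- if (omega > 0) u else 1 - u
  mu + sign(omega) * (stats::qgamma(us, shape = k, scale = theta) - k * theta)
}

#' Quantile function of the mean-one shifted log-normal receptor distribution
#'
#' Receptor counts are measured relative to the population average, so the
#' untruncated mean is constrained to 1: the log-normal component
#' `exp(mu_R + sigma_R * qnorm(u))` is shifted by
#' `s = 1 - exp(mu_R + sigma_R^2 / 2)`.
#'
#' @param u Probabilities in (0, 1).
#' @param mu_R,sigma_R Log-scale location and scale, `sigma_R > 0`.
#' @return Quantiles of the shifted log-normal distribution.
#' @export
qreceptor <- function(u, mu_R, sigma_R) {
  if (any(u <= 0) || any(u >= 1)) stop("'u' must lie in (0, 1)")
  if (sigma_R < 0) stop("'sigma_R' must be non-negative")
  if (sigma_R == 0) return(rep(1, length(u)))
  s <- 1 - exp(mu_R + sigma_R^2 / 2)
  s + exp(mu_R + sigma_R * stats::qnorm(u))
}

#' Copula correlation matrix of the cell-property vector
#'
#' Builds the 3x3 correlation matrix of the Gaussian copula over
#' \eqn{(R, \lambda, \beta)}. The receptor/recycling entry is derived as
#' \deqn{\rho_{R\beta} = \rho_{R\lambda}\rho_{\lambda\beta} +
#'   \tilde\rho_{R\beta}\sqrt{(1-\rho_{R\lambda}^2)(1-\rho_{\lambda\beta}^2)},}
#' the partial-correlation construction that keeps the matrix positive
#' definite for any inputs in the open cube (-1, 1)^3.
#'
#' @param rho_Rlam,rho_lambeta,rho_tilde_Rbeta Dependence parameters in
#'   (-1, 1).
#' @return A 3x3 symmetric positive-definite correlation matrix with
#'   dimnames `R`, `lam`, `beta`.
#' @examples
#' copula_correlation(0, 0, 0.4)["R", "beta"]  # 0.4
#' @export
copula_correlation <- function(rho_Rlam, rho_lambeta, rho_tilde_Rbeta) {
  rho <- c(rho_Rlam, rho_lambeta, rho_tilde_Rbeta)
  if (any(!is.finite(rho)) || any(rho <= -1) || any(rho >= 1)) {
    stop("all dependence parameters must lie in (-1, 1)")
  }
  rho_Rbeta <- rho_Rlam * rho_lambeta +
    rho_tilde_Rbeta * sqrt((1 - rho_Rlam^2) * (1 - rho_lambeta^2))
  P <- matrix(c(
    1, rho_Rlam, rho_Rbeta,
    rho_Rlam, 1, rho_lambeta,
    rho_Rbeta, rho_lambeta, 1
  ), 3, 3, dimnames = list(c("R", "lam", "beta"), c("R", "lam", "beta")))
  P
}

#' Sample a heterogeneous cell population
#'
#' Draws per-cell properties \eqn{(R_i, \lambda_i, \beta_i)} from the Gaussian
#' copula model: correlated standard-normal triples with correlation matrix
#' [copula_correlation()] are mapped through the normal CDF to uniforms and
#' then through the marginal quantile functions ([qreceptor()],
#' [qshifted_gamma()]). Triples with any negative component are rejected and
#' redrawn, truncating the population to non-negative properties while
#' preserving the copula dependence among accepted cells.
#'
#' @param pp A [population_params()] object.
#' @param n Number of cells to return.
#' @param seed Optional integer seed for reproducibility.
#' @return A data frame with `n` rows and columns `R`, `lam`, `beta`.
#' @examples
#' pp <- population_params(-0.25, 0.5, 0.1, 0.02, 0, 0.05, 0.01, 0,
#'                         p = 0.05)
#' cells <- sample_cells(pp, 5, seed = 1)
#' @export
sample_cells <- function(pp, n, seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  P <- copula_correlation(pp$rho_Rlam, pp$rho_lambeta, pp$rho_tilde_Rbeta)
  L <- chol(P)
  # marginal transform from the copula z-score; the normal-limit branches use
  # z directly, avoiding the pnorm/qnorm round trip of the general path
  q_rate <- function(z, mu, sigma, omega) {
    if (sigma == 0) return(rep(mu, length(z)))
    if (abs(omega) < 1e-3) return(mu + sigma * z)
    u <- pmin(pmax(stats::pnorm(z), 1e-15), 1 - 1e-15)
    qshifted_gamma(u, mu, sigma, omega)
  }
  out <- matrix(NA_real_, 0, 3)
  drawn <- 0L
  accepted <- 0L
  while (nrow(out) < n) {
    todo <- n - nrow(out)
    m <- max(todo, ceiling(1.2 * todo))
    Z <- matrix(stats::rnorm(3 * m), m, 3) %*% L
    R <- if (pp$sigma_R == 0) rep(1, m)
         else 1 - exp(pp$mu_R + pp$sigma_R^2 / 2) +
           exp(pp$mu_R + pp$sigma_R * Z[, 1])
    lam <- q_rate(Z[, 2], pp$mu_lam, pp$sigma_lam, pp$omega_lam)
    beta <- q_rate(Z[, 3], pp$mu_beta, pp$sigma_beta, pp$omega_beta)
    keep <- R >= 0 & lam >= 0 & beta >= 0
    drawn <- drawn + m
    accepted <- accepted + sum(keep)
    if (drawn >= 1000 && accepted / drawn < 1e-3) {
      stop("truncation acceptance rate below 1e-3; pathological population parameters")
    }
    out <- rbind(out, cbind(R, lam, beta)[keep, , drop = FALSE])
  }
  out <- out[seq_len(n), , drop = FALSE]
  data.frame(R = out[, 1], lam = out[, 2], beta = out[, 3])
}

#' Serialize population parameters to a flat named vector
#'
#' @param pp A [population_params()] object.
#' @return A named numeric vector of the 12 population parameters.
#' @export
as_theta <- function(pp) {
  unlist(pp[c("mu_R", "sigma_R", "mu_lam", "sigma_lam", "omega_lam",
              "mu_beta", "sigma_beta", "omega_beta",
              "rho_Rlam", "rho_lambeta", "rho_tilde_Rbeta", "p")])
}

#' Rebuild population parameters from a flat named vector
#'
#' Inverse of [as_theta()]; extra elements (e.g. measurement-scale entries of
#' a full ABC parameter vector) are ignored.
#'
#' @param theta Named numeric vector containing at least the 12 population
#'   parameter names.
#' @return A [population_params()] object.
#' @export
theta_to_population <- function(theta) {
  population_params(
    mu_R = theta[["mu_R"]], sigma_R = theta[["sigma_R"]],
    mu_lam = theta[["mu_lam"]], sigma_lam = theta[["sigma_lam"]],
    omega_lam = theta[["omega_lam"]],
    mu_beta = theta[["mu_beta"]], sigma_beta = theta[["sigma_beta"]],
    omega_beta = theta[["omega_beta"]],
    rho_Rlam = theta[["rho_Rlam"]], rho_lambeta = theta[["rho_lambeta"]],
    rho_tilde_Rbeta = theta[["rho_tilde_Rbeta"]], p = theta[["p"]]
  )
}
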