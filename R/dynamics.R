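#' Kinetic parameters for a single cell
#'
#' Bundles the per-cell dynamical rates of the internalization/recycling
#' compartment model: the internalization rate \eqn{\lambda} (per minute), the
#' recycling rate \eqn{\beta} (per minute), and the disassociation probability
#' \eqn{p} (the probability that a recycling event releases free antibody
#' inside the cell).
#'
#' @param lam Internalization rate, min^-1, non-negative.
#' @param beta Recycling rate, min^-1, non-negative.
#' @param p Disassociation probability in \[0, 1\].
#'
#' @return An object of class `"kinetic_params"`: a named list with elements
#'   `lam`, `beta`, `p`.
#' @examples
#' kinetic_params(lam = 0.106, beta = 0.047, p = 0.068)
#' @export
kinetic_params <- function(lam, beta, p) {
  stopifnot(is.numeric(lam), is.numeric(beta), is.numeric(p))
  if (any(lam < 0) || any(beta < 0)) {
    stop("rates 'lam' and 'beta' must be non-negative")
  }
  if (any(p < 0) || any(p > 1)) {
    stop("'p' must lie in [0, 1]")
  }
  structure(list(lam = lam, beta = beta, p = p), class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Kinetic parameters: lambda =", format(x$lam), "/min, beta =",
      format(x$beta), "/min, p =", format(x$p), "\n")
  invisible(x)
}

#' Equilibrium initial state of the compartment model
#'
#' Before antibody exposure the receptor pool is at steady state between
#' internalization and recycling, so the surface fraction is
#' \eqn{S(0) = \beta / (\lambda + \beta)} and the internal transferrin-bound
#' fraction is \eqn{T(0) = 1 - S(0)}. No antibody has been endocytosed
#' (\eqn{E(0) = 0}) and no free antibody has accumulated (\eqn{F(0) = 0}).
#'
#' @param k A [kinetic_params()] object (vectorized components allowed).
#' @return A list with components `T`, `S`, `E`, `F` (fractions of the total
#'   receptor count; `T + S + E = 1`).
#' @examples
#' equilibrium_state(kinetic_params(0.106, 0.047, 0.068))$S  # about 0.31
#' @export
equilibrium_state <- function(k) {
  if (any(k$lam + k$beta <= 0)) {
    stop("equilibrium undefined when lam + beta = 0")
  }
  S <- k$beta / (k$lam + k$beta)
  list(T = 1 - S, S = S, E = rep(0, length(S)), F = rep(0, length(S)))
}

## Closed-form solution of
##   dT/dt = -beta T
##   dS/dt =  beta T - lam S + p beta E
##   dE/dt =  lam S - p beta E
##   dF/dt =  p beta E
## T decouples; S + E = 1 - T by conservation, so S obeys the scalar ODE
##   dS/dt = -(lam + p beta) S + p beta + beta (1 - p) T0 e^{-beta t},
## solvable in closed form; F is the analytic integral of p beta E.
## Vectorized over cells (lam, beta, p vectors) and times.
.solve_kinetics_core <- function(lam, beta, p, times) {
  n <- length(lam)
  m <- length(times)
  S0 <- beta / (lam + beta)
  T0 <- 1 - S0
  kk <- lam + p * beta           # relaxation rate of S
  cc <- p * beta                 # constant forcing (stationary S level cc/kk)
  dd <- beta * (1 - p) * T0      # coefficient of the e^{-beta t} forcing

  tt <- matrix(times, n, m, byrow = TRUE)
  Ebt <- exp(-beta * tt)         # e^{-beta t}, n x m
  Ekt <- exp(-kk * tt)

  Tt <- T0 * Ebt

  delta <- kk - beta
  # non-resonant closed form; resonant (kk == beta) limit handled below
  safe <- abs(delta) > 1e-8 * pmax(kk, beta, 1e-300)
  dnz <- ifelse(safe, delta, 1)  # placeholder to avoid 0/0; overwritten below
  Sinf <- cc / pmax(kk, 1e-300)
  a2 <- dd / dnz                 # coefficient of e^{-beta t}
  a1 <- S0 - Sinf - a2           # coefficient of e^{-k t}
  St <- Sinf + a1 * Ekt + a2 * Ebt
  # integral of S from 0 to t (for F)
  intS <- Sinf * tt +
    a1 * (1 - Ekt) / pmax(kk, 1e-300) +
    a2 * (1 - Ebt) / pmax(beta, 1e-300)

  if (any(!safe)) {
    # resonance kk -> beta: d e^{-beta t} forcing at the natural rate gives a
    # t e^{-beta t} secular term
    i <- which(!safe)
    bi <- beta[i]; di <- dd[i]; S0i <- S0[i]; Si <- Sinf[i]
    ti <- tt[i, , drop = FALSE]
    Eb <- exp(-bi * ti)
    St[i, ] <- Si + (S0i - Si) * Eb + di * ti * Eb
    intS[i, ] <- Si * ti + (S0i - Si) * (1 - Eb) / bi +
      di * (1 - (1 + bi * ti) * Eb) / bi^2
  }

  # kk == 0 only when lam = 0 and p*beta = 0 (beta > 0 since equilibrium
  # requires lam + beta > 0): dS/dt = beta T0 e^{-beta t}
  zero_k <- kk <= 0
  if (any(zero_k)) {
    i <- which(zero_k)
    ti <- tt[i, , drop = FALSE]
    bi <- beta[i]; T0i <- T0[i]; S0i <- S0[i]
    Eb <- exp(-bi * ti)
    St[i, ] <- S0i + T0i * (1 - Eb)
    intS[i, ] <- S0i * ti + T0i * (ti - (1 - Eb) / bi)
  }

  Et <- 1 - Tt - St
  Ft <- p * beta * (tt - T0 * (1 - Ebt) / pmax(beta, 1e-300) - intS)
  # beta = 0: T frozen, F = 0
  b0 <- beta == 0
  if (any(b0)) Ft[b0, ] <- 0
  Ft[Ft < 0] <- 0                # clip numerical negatives of order eps
  Et[Et < 0] <- 0

  list(T = Tt, S = St, E = Et, F = Ft)
}

#' Solve the internalization/recycling compartment model
#'
#' Computes the exact solution of the linear compartment system
#' \deqn{dT/dt = -\beta T,\quad dS/dt = \beta T - \lambda S + p\beta E,\quad
#'       dE/dt = \lambda S - p\beta E,\quad dF/dt = p\beta E,}
#' starting from the receptor equilibrium ([equilibrium_state()]). `T` is the
#' internal transferrin-bound receptor fraction, `S` the surface antibody-bound
#' fraction, `E` the endocytosed antibody-bound fraction, and `F` the internal
#' free antibody, all relative to the cell's total receptor count. The solution
#' uses the closed form obtained from the decoupled `T` equation and receptor
#' conservation (`T + S + E = 1`), equivalent to the matrix exponential
#' `x0 exp(Mt)` of the linear system.
#'
#' @param k A [kinetic_params()] object.
#' @param times Numeric vector of observation times (minutes), sorted,
#'   non-negative.
#' @return An object of class `"trajectory"`: a data frame with columns
#'   `time`, `T`, `S`, `E`, `F`, plus the derived totals `A = S + E + F`
#'   (total bound antibody) and `I = E + F` (internal antibody).
#' @examples
#' tr <- solve_kinetics(kinetic_params(0.106, 0.047, 0.068), c(0, 10, 30, 120))
#' tr$A - tr$I  # surface-bound antibody S(t)
#' @export
solve_kinetics <- function(k, times) {
  stopifnot(is.numeric(times))
  if (any(times < 0)) stop("'times' must be non-negative")
  if (is.unsorted(times)) stop("'times' must be sorted increasing")
  if (length(k$lam) != 1L) stop("solve_kinetics() expects scalar parameters; use cell_trajectories() for populations")
  sol <- .solve_kinetics_core(k$lam, k$beta, k$p, times)
  out <- data.frame(
    time = times,
    T = drop(sol$T), S = drop(sol$S), E = drop(sol$E), F = drop(sol$F)
  )
  out$A <- out$S + out$E + out$F
  out$I <- out$E + out$F
  class(out) <- c("trajectory", "data.frame")
  out
}

#' Compartment states for many cells at once
#'
#' Vectorized form of [solve_kinetics()] used by the forward simulator: solves
#' the compartment model for every cell of a sampled population at a common
#' set of times.
#'
#' @param cells A data frame with columns `R`, `lam`, `beta` (one row per
#'   cell), as returned by [sample_cells()].
#' @param p Shared disassociation probability.
#' @param times Numeric vector of times (minutes).
#' @return A list of `n_cells x n_times` matrices `T`, `S`, `E`, `F`, `A`, `I`.
#' @export
cell_trajectories <- function(cells, p, times) {
  if (any(times < 0)) stop("'times' must be non-negative")
  sol <- .solve_kinetics_core(cells$lam, cells$beta, rep(p, length.out = nrow(cells)), times)
  sol$A <- sol$S + sol$E + sol$F
  sol$I <- sol$E + sol$F
  sol
}
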