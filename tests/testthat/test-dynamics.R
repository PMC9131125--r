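test_that("equilibrium initial state follows beta/(lam+beta)", {
  eq <- equilibrium_state(ref_kinetics())
  expect_equal(eq$S, 0.047 / 0.153, tolerance = 1e-12)
  expect_equal(eq$S, 0.31, tolerance = 0.01)
  expect_equal(eq$T + eq$S + eq$E, 1)
  expect_equal(eq$E, 0)
  expect_equal(eq$F, 0)

  # no internalization: all receptors surface-bound
  eq0 <- equilibrium_state(kinetic_params(0, 0.05, 0))
  expect_equal(eq0$S, 1)
  expect_equal(eq0$T, 0)

  # symmetric rates
  expect_equal(equilibrium_state(kinetic_params(0.2, 0.2, 0))$S, 0.5)

  expect_error(equilibrium_state(kinetic_params(0, 0, 0)), "equilibrium")
})

test_that("solution starts at equilibrium and rejects bad inputs", {
  k <- ref_kinetics()
  tr <- solve_kinetics(k, c(0, 10))
  eq <- equilibrium_state(k)
  expect_equal(tr$S[1], eq$S)
  expect_equal(tr$T[1], eq$T)
  expect_equal(tr$A[1], eq$S)   # A(0) = S(0)
  expect_equal(tr$I[1], 0)
  expect_error(solve_kinetics(k, c(-1, 0)), "non-negative")
  expect_error(kinetic_params(-0.1, 0.05, 0), "non-negative")
  expect_error(kinetic_params(0.1, 0.05, 1.2), "p")
})

test_that("no disassociation means no free antibody and A -> 1", {
  k <- kinetic_params(0.2, 0.08, 0)
  tr <- solve_kinetics(k, c(0, 10, 100, 1000, 5000))
  expect_true(all(tr$F == 0))
  expect_lt(abs(tr$A[5] - 1), 1e-10)
})

test_that("closed form matches an adaptive numeric integrator on random rates", {
  skip_if_not_installed("deSolve")
  set.seed(71)
  rhs <- function(t, y, par) {
    with(as.list(c(y, par)), list(c(
      -beta * T,
      beta * T - lam * S + p * beta * E,
      lam * S - p * beta * E,
      p * beta * E)))
  }
  times <- c(0, 1, 5, 10, 30, 60, 120)
  worst <- 0
  for (i in 1:100) {
    lam <- runif(1, 0, 0.5); beta <- runif(1, 1e-3, 0.5); p <- runif(1, 0, 1)
    tr <- solve_kinetics(kinetic_params(lam, beta, p), times)
    y0 <- unlist(equilibrium_state(kinetic_params(lam, beta, p)))
    num <- deSolve::ode(c(T = y0[["T"]], S = y0[["S"]], E = 0, F = 0),
                        times, rhs, c(lam = lam, beta = beta, p = p),
                        rtol = 1e-11, atol = 1e-12)
    worst <- max(worst,
                 max(abs(as.matrix(tr[, c("T", "S", "E", "F")]) -
                           num[, c("T", "S", "E", "F")])))
  }
  expect_lt(worst, 1e-8)
})

test_that("closed form matches the matrix exponential, including resonance", {
  skip_if_not_installed("Matrix")
  cases <- list(c(0.106, 0.047, 0.068),
                c(0.05, 0.1, 0.5),      # lam + p*beta == beta exactly
                c(0.3, 0.01, 1))
  for (cs in cases) {
    lam <- cs[1]; beta <- cs[2]; p <- cs[3]
    M <- matrix(c(-beta, 0, 0, 0,
                  beta, -lam, p * beta, 0,
                  0, lam, -p * beta, 0,
                  0, 0, p * beta, 0), 4, 4, byrow = TRUE)
    k <- kinetic_params(lam, beta, p)
    y0 <- unlist(equilibrium_state(k))
    for (t in c(1, 10, 120)) {
      ex <- as.numeric(Matrix::expm(M * t) %*% y0)
      tr <- solve_kinetics(k, t)
      expect_equal(as.numeric(tr[1, c("T", "S", "E", "F")]), ex,
                   tolerance = 1e-9)
    }
  }
})

test_that("receptor conservation and monotonicity hold on random parameters", {
  set.seed(72)
  times <- sort(c(0, runif(20, 0, 200)))
  for (i in 1:50) {
    k <- kinetic_params(runif(1, 0, 0.5), runif(1, 1e-3, 0.5), runif(1, 0, 1))
    tr <- solve_kinetics(k, times)
    expect_lt(max(abs(tr$T + tr$S + tr$E - 1)), 1e-10)
    expect_true(all(diff(tr$A) > -1e-10))
    expect_true(all(diff(tr$I) > -1e-10))
    expect_true(all(diff(tr$F) > -1e-10))
    expect_true(all(diff(tr$T) < 1e-10))
    expect_true(all(tr$I <= tr$A + 1e-12))
    expect_true(all(as.matrix(tr[, c("T", "S", "E", "F")]) >= -1e-12))
  }
})

test_that("late-time behaviour: T vanishes and antibody accumulates linearly", {
  k <- kinetic_params(0.106, 0.047, 0.068)
  tr <- solve_kinetics(k, c(500, 600, 700, 800))
  expect_lt(max(tr$T), 1e-8)
  # dF/dt approaches a positive constant: equal time steps, equal increments
  dF <- diff(tr$F)
  expect_gt(min(dF), 0)
  expect_lt(max(abs(dF - mean(dF))), 1e-6 * mean(dF))
})

test_that("vectorized population solver agrees with the scalar path", {
  cells <- data.frame(R = c(1, 1.5), lam = c(0.1, 0.2), beta = c(0.05, 0.03))
  times <- c(0, 15, 60)
  tr <- cell_trajectories(cells, p = 0.1, times)
  for (i in 1:2) {
    one <- solve_kinetics(kinetic_params(cells$lam[i], cells$beta[i], 0.1),
                          times)
    expect_equal(tr$S[i, ], one$S, tolerance = 1e-12)
    expect_equal(tr$F[i, ], one$F, tolerance = 1e-12)
    expect_equal(tr$A[i, ], one$A, tolerance = 1e-12)
  }
})
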