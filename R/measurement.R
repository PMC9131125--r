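#' Flow-cytometry measurement parameters
#'
#' Parameters of the probabilistic observation model mapping per-cell antibody
#' amounts to two-channel fluorescence: channel scale factors, quench
#' efficiency and multiplicative photomultiplier (PMT) noise magnitudes.
#'
#' @param alpha1 Q-channel (quenchable probe) scale, fluorescence units per
#'   unit antibody-per-receptor; > 0.
#' @param alpha2 U-channel (unquenchable probe) scale; > 0.
#' @param eta Quench efficiency in \[0, 1\]: the fraction of surface-bound
#'   Q-probe fluorescence removed by the quencher dye.
#' @param sigma1,sigma2 Channel noise coefficients of variation (>= 0). PMT
#'   shot noise is modelled as multiplicative Gaussian noise with constant
#'   squared coefficient of variation: `observed = true * (1 + eps)`,
#'   `eps ~ Normal(0, sigma^2)`.
#' @param noise Either `"multiplicative"` (default; constant CV, matching the
#'   amplification model) or `"sqrt"`, an alternative in which the noise SD
#'   scales with the square root of the true signal
#'   (`observed = true + eps * sigma * sqrt(true)`).
#'
#' @return An object of class `"measurement_params"`.
#' @export
measurement_params <- function(alpha1, alpha2, eta, sigma1, sigma2,
                               noise = c("multiplicative", "sqrt")) {
  noise <- match.arg(noise)
  if (alpha1 <= 0 || alpha2 <= 0) stop("channel scales must be positive")
  if (eta < 0 || eta > 1) stop("'eta' must lie in [0, 1]")
  if (sigma1 < 0 || sigma2 < 0) stop("noise coefficients must be non-negative")
  structure(list(alpha1 = alpha1, alpha2 = alpha2, eta = eta,
                 sigma1 = sigma1, sigma2 = sigma2, noise = noise),
            class = "measurement_params")
}

#' @export
print.measurement_params <- function(x, ...) {
  cat(sprintf(
    "Measurement model: alpha1 = %g, alpha2 = %g, eta = %g, sigma1 = %g, sigma2 = %g (%s noise)\n",
    x$alpha1, x$alpha2, x$eta, x$sigma1, x$sigma2, x$noise))
  invisible(x)
}

## noise-free ("true") signals per channel
## quenched Q keeps internal antibody plus the unquenched fraction (1 - eta)
## of the surface-bound signal; U is unaffected by the quencher
.true_signals <- function(A, I, S, R, mp, condition) {
  q <- if (condition == "quenched") {
    mp$alpha1 * (I + (1 - mp$eta) * S) * R
  } else {
    mp$alpha1 * A * R
  }
  u <- mp$alpha2 * A * R
  list(Q = q, U = u)
}

.apply_noise <- function(true, sigma, mp) {
  if (sigma == 0) return(true)
  eps <- stats::rnorm(length(true), 0, sigma)
  if (mp$noise == "multiplicative") true * (1 + eps) else true + eps * sqrt(pmax(true, 0))
}

#' Observe cells through the flow-cytometry noise model
#'
#' Maps noise-free per-cell compartment amounts to observed two-channel
#' fluorescence: the true signal (scaled by the per-cell receptor count and,
#' for the quenched condition, attenuated by the quench efficiency) is
#' perturbed by multiplicative PMT noise independently per channel, then an
#' autofluorescence pair is added jointly, preserving the empirical
#' between-channel autofluorescence correlation.
#'
#' @param cells Data frame of per-cell properties (column `R`).
#' @param A,I,S Numeric vectors: total bound antibody, internal antibody and
#'   surface-bound antibody per cell (from [cell_trajectories()]).
#' @param mp A [measurement_params()] object.
#' @param condition `"quenched"` or `"unquenched"`.
#' @param af Autofluorescence control: data frame with columns `EQ`, `EU`, or
#'   `NULL` for no background. Pairs are resampled jointly with replacement.
#' @return A data frame with columns `Q` and `U` (observed fluorescence; may
#'   be negative, as amplified cytometry output can dip below zero).
#' @export
observe_cells <- function(cells, A, I, S, mp,
                          condition = c("unquenched", "quenched"),
                          af = NULL) {
  condition <- match.arg(condition)
  sig <- .true_signals(A, I, S, cells$R, mp, condition)
  Q <- .apply_noise(sig$Q, mp$sigma1, mp)
  U <- .apply_noise(sig$U, mp$sigma2, mp)
  if (!is.null(af) && nrow(af) > 0) {
    idx <- sample.int(nrow(af), length(Q), replace = TRUE)
    Q <- Q + af$EQ[idx]
    U <- U + af$EU[idx]
  }
  data.frame(Q = Q, U = U)
}

#' Geometric mean fluorescence intensity
#'
#' The standard scalar summary of a cytometry fluorescence distribution:
#' `exp(mean(log(v)))` over the strictly positive values. Non-positive values
#' (possible after noise and background subtraction) are excluded; their count
#' is attached as attribute `n_excluded`.
#'
#' @param values Numeric fluorescence sample.
#' @return The geometric mean of the positive values, with attribute
#'   `n_excluded`.
#' @examples
#' gmfi(c(1, 10, 100))  # 10
#' @export
gmfi <- function(values) {
  pos <- values[is.finite(values) & values > 0]
  if (length(pos) == 0) stop("gmfi() needs at least one positive value")
  structure(exp(mean(log(pos))), n_excluded = length(values) - length(pos))
}

#' Estimate quench efficiency from a 4 degree C control
#'
#' With internalization inhibited (cells kept at 4 degrees C) all probe is
#' surface-bound, so comparing the autofluorescence-corrected GMFI of quenched
#' and unquenched control samples isolates the fraction of surface signal the
#' quencher removes:
#' `eta = 1 - (GMFI_quenched - GMFI_af) / (GMFI_unquenched - GMFI_af)`,
#' clamped to \[0, 1\].
#'
#' @param q_gmfi_4C GMFI of the quenched 4C control sample.
#' @param u_gmfi_4C GMFI of the unquenched 4C control sample; must exceed
#'   `af_gmfi`.
#' @param af_gmfi GMFI of the autofluorescence control.
#' @return Estimated quench efficiency in \[0, 1\].
#' @export
estimate_quench_efficiency <- function(q_gmfi_4C, u_gmfi_4C, af_gmfi) {
  if (u_gmfi_4C <= af_gmfi) {
    stop("unquenched 4C control GMFI must exceed the autofluorescence GMFI")
  }
  eta <- 1 - (q_gmfi_4C - af_gmfi) / (u_gmfi_4C - af_gmfi)
  min(max(eta, 0), 1)
}

#' Assemble a snapshot dataset
#'
#' Container for a complete internalization-assay dataset: per-(time,
#' condition) paired two-channel snapshots, the autofluorescence control
#' sample, and the 4C quench-efficiency control GMFIs.
#'
#' @param snapshots Data frame with columns `time_min`, `condition`
#'   (`"quenched"`/`"unquenched"`), `Q`, `U`; both conditions must be present
#'   at every time.
#' @param autofluorescence Data frame with columns `EQ`, `EU`.
#' @param quench_control Optional named list with elements `q_gmfi` and
#'   `u_gmfi` (GMFIs of the 4C quenched/unquenched controls).
#' @param truth Optional list of generating parameters and per-cell latents
#'   (kept by the synthetic-data generator for recovery tests).
#' @return An object of class `"ship_dataset"`.
#' @export
ship_dataset <- function(snapshots, autofluorescence = NULL,
                         quench_control = NULL, truth = NULL) {
  need <- c("time_min", "condition", "Q", "U")
  if (!all(need %in% names(snapshots))) {
    stop("'snapshots' must have columns ", paste(need, collapse = ", "))
  }
  tab <- table(unique(snapshots[c("time_min", "condition")])$time_min)
  if (any(tab < 2)) {
    stop("both conditions must be present at every observation time")
  }
  structure(list(snapshots = snapshots,
                 autofluorescence = autofluorescence,
                 quench_control = quench_control,
                 truth = truth),
            class = "ship_dataset")
}

#' @export
print.ship_dataset <- function(x, ...) {
  times <- sort(unique(x$snapshots$time_min))
  cat("Internalization assay snapshot dataset\n")
  cat("  times (min):", paste(times, collapse = ", "), "\n")
  cat("  cells:", nrow(x$snapshots), "across",
      nrow(unique(x$snapshots[c("time_min", "condition")])), "samples\n")
  if (!is.null(x$autofluorescence)) {
    cat("  autofluorescence control:", nrow(x$autofluorescence), "cells\n")
  }
  if (!is.null(x$truth)) cat("  ground truth attached\n")
  invisible(x)
}

#' Extract the GMFI series of the quenchable channel
#'
#' Summarizes a snapshot dataset into the homogeneous-model observable: the
#' Q-channel GMFI at each (time, condition).
#'
#' @param data A [ship_dataset()].
#' @return Data frame with columns `time_min`, `condition`, `gmfi`.
#' @export
gmfi_series <- function(data) {
  snaps <- data$snapshots
  agg <- aggregate(snaps$Q, by = snaps[c("time_min", "condition")],
                   FUN = function(v) as.numeric(gmfi(v)))
  names(agg)[3] <- "gmfi"
  agg[order(agg$time_min, agg$condition), ]
}

#' Write / read a snapshot dataset as plain CSV files
#'
#' `write_ship_dataset()` writes `snapshots.csv` (columns `time_min`,
#' `condition`, `Q`, `U`), `autofluorescence.csv` (columns `EQ`, `EU`), an
#' optional `truth.json`, and a small `manifest.yaml` listing files, times and
#' cell counts. `read_ship_dataset()` reads the same layout back.
#'
#' @param data A [ship_dataset()].
#' @param dir Directory to write to / read from (created if missing).
#' @return `write_ship_dataset()` returns `dir` invisibly;
#'   `read_ship_dataset()` returns a [ship_dataset()].
#' @export
write_ship_dataset <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(data$snapshots, file.path(dir, "snapshots.csv"),
                   row.names = FALSE)
  if (!is.null(data$autofluorescence)) {
    utils::write.csv(data$autofluorescence,
                     file.path(dir, "autofluorescence.csv"), row.names = FALSE)
  }
  if (!is.null(data$truth)) {
    jsonlite::write_json(data$truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  manifest <- list(
    files = list(snapshots = "snapshots.csv",
                 autofluorescence = if (!is.null(data$autofluorescence))
                   "autofluorescence.csv"),
    times_min = sort(unique(data$snapshots$time_min)),
    n_cells = nrow(data$snapshots),
    quench_control = data$quench_control
  )
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' @rdname write_ship_dataset
#' @export
read_ship_dataset <- function(dir) {
  snaps <- utils::read.csv(file.path(dir, "snapshots.csv"))
  af_path <- file.path(dir, "autofluorescence.csv")
  af <- if (file.exists(af_path)) utils::read.csv(af_path) else NULL
  man_path <- file.path(dir, "manifest.yaml")
  qc <- NULL
  if (file.exists(man_path)) {
    man <- yaml::read_yaml(man_path)
    qc <- man$quench_control
  }
  truth <- NULL
  tj <- file.path(dir, "truth.json")
  if (file.exists(tj)) truth <- jsonlite::read_json(tj, simplifyVector = TRUE)
  ship_dataset(snaps, af, quench_control = qc, truth = truth)
}
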