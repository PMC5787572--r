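# Joint-angle processing: 5 Hz smoothing, numerical differentiation,
# normalized-cycle averaging, windowed peak angular accelerations and
# quadratic speed trends.

#' Smooth a marker or joint-angle trajectory
#'
#' Zero-phase 4th-order Butterworth low-pass at `cutoff` Hz (default 5,
#' the conventional marker-data cutoff).
#'
#' @param x Numeric vector.
#' @param fs Sampling rate, Hz (> 2 * cutoff).
#' @param cutoff Low-pass cutoff, Hz.
#' @return Smoothed vector of the same length.
#' @export
smooth_trajectory <- function(x, fs, cutoff = 5) {
  if (anyNA(x) || any(!is.finite(x))) {
    stop("trajectory contains non-finite values", call. = FALSE)
  }
  if (fs <= 2 * cutoff) stop("fs must exceed twice the cutoff",
                             call. = FALSE)
  zero_phase_filter(x, fs, cutoff, "low")
}

#' Differentiate a trajectory to velocity and acceleration
#'
#' Central differences at the native sampling rate (one-sided at the
#' endpoints), preserving physical units: deg/s and deg/s².
#'
#' @param x Angle vector, degrees (>= 5 samples).
#' @param fs Sampling rate, Hz.
#' @return List with `velocity` and `acceleration`, same length as `x`.
#' @export
differentiate <- function(x, fs) {
  n <- length(x)
  if (n < 5L) stop("need at least 5 samples", call. = FALSE)
  dt <- 1 / fs
  mid <- 2:(n - 1L)
  v <- numeric(n)
  v[mid] <- (x[mid + 1L] - x[mid - 1L]) / (2 * dt)
  v[1] <- (x[2] - x[1]) / dt
  v[n] <- (x[n] - x[n - 1L]) / dt
  a <- numeric(n)
  a[mid] <- (x[mid + 1L] - 2 * x[mid] + x[mid - 1L]) / dt^2
  a[1] <- a[2]
  a[n] <- a[n - 1L]
  list(velocity = v, acceleration = a)
}

#' Average a signal over normalized gait cycles
#'
#' Time-normalizes each heel-contact-delimited cycle to `n_bins` points
#' and averages across cycles.
#'
#' @param x Numeric vector (angle, velocity or acceleration samples).
#' @param heel_contacts Strictly increasing sample indices of cycle
#'   starts; cycle k spans `[hc[k], hc[k+1])`.
#' @param n_bins Points per cycle (default 100).
#' @return Numeric vector of length `n_bins`.
#' @export
normalize_cycle_average <- function(x, heel_contacts, n_bins = 100L) {
  spans <- lapply(seq_len(length(heel_contacts) - 1L), function(k) {
    c(heel_contacts[k], heel_contacts[k + 1L])
  })
  mat <- time_normalize(matrix(x, nrow = 1L), spans, n_bins)
  rowMeans(matrix(mat[1, ], nrow = n_bins))
}

#' Default windows for the eleven peak angular accelerations
#'
#' Phase windows (% gait cycle) within which the main peak angular
#' accelerations are sought: both directions of all three joints within
#' the stance phase, the propulsion/swing-initiation peaks within
#' pre-swing, and the deceleration peaks within late swing.  Window
#' boundaries are configuration defaults — the stance window is 0-30%,
#' pre-swing 45-65%, late-swing 85-100%.
#'
#' @return Data frame with `label` (P1..P11), `joint`, `direction`
#'   (`"positive"` = dorsiflexion/flexion, `"negative"` =
#'   plantarflexion/extension), `phase`, `lo`, `hi`.
#' @export
default_peak_windows <- function() {
  data.frame(
    label = paste0("P", 1:11),
    joint = c("ankle", "ankle", "knee", "knee", "hip", "hip",
              "ankle", "knee", "knee", "knee", "hip"),
    direction = c("positive", "negative", "positive", "negative",
                  "positive", "negative",
                  "negative", "positive",
                  "negative", "positive", "negative"),
    phase = c(rep("stance", 6), rep("pre-swing", 2),
              rep("late-swing", 3)),
    lo = c(rep(0, 6), 45, 45, 85, 85, 85),
    hi = c(rep(30, 6), 65, 65, 100, 100, 100))
}

#' Windowed peak angular accelerations over the normalized cycle
#'
#' For each labeled (joint, direction, phase window) the extremum of the
#' signed acceleration within the window is located; a peak sitting on a
#' window edge is flagged as a boundary peak.
#'
#' @param acc Named list of 100-bin cycle-averaged accelerations, one per
#'   joint (deg/s²), or a single vector when `windows` names one joint.
#' @param windows Data frame as in [default_peak_windows()].
#' @return Data frame with `label`, `joint`, `direction`, `timing`
#'   (% gait cycle), `magnitude` (signed deg/s²), `boundary` flag.
#' @export
find_peak_accelerations <- function(acc, windows = default_peak_windows()) {
  if (!is.list(acc)) acc <- setNames(list(acc), unique(windows$joint)[1])
  out <- windows[, c("label", "joint", "direction")]
  out$timing <- NA_real_
  out$magnitude <- NA_real_
  out$boundary <- NA
  n_bins <- length(acc[[1]])
  pct <- seq_len(n_bins) * 100 / n_bins
  for (i in seq_len(nrow(windows))) {
    w <- windows[i, ]
    a <- acc[[w$joint]]
    if (is.null(a)) stop(sprintf("no acceleration for joint '%s'", w$joint),
                         call. = FALSE)
    idx <- which(pct >= w$lo & pct <= w$hi)
    if (length(idx) == 0L) {
      stop(sprintf("empty window %s (%g-%g%%)", w$label, w$lo, w$hi),
           call. = FALSE)
    }
    signed <- if (w$direction == "positive") a[idx] else -a[idx]
    k <- idx[which.max(signed)]
    out$timing[i] <- pct[k]
    out$magnitude[i] <- a[k]
    out$boundary[i] <- k == idx[1] || k == idx[length(idx)]
  }
  out
}

#' Quadratic trend of peak acceleration versus walking speed
#'
#' Ordinary least-squares fit of `magnitude ~ speed + speed^2`.
#'
#' @param speed Walking speeds, km/h (>= 3 distinct values).
#' @param magnitude Peak magnitudes at those speeds.
#' @return List with `coefficients` (intercept, linear, quadratic),
#'   `fitted`, and the `lm` object as `model`.
#' @export
fit_speed_trend <- function(speed, magnitude) {
  if (length(unique(speed)) < 3L) {
    stop("need at least 3 distinct speeds for a quadratic fit",
         call. = FALSE)
  }
  d <- data.frame(speed = speed, magnitude = magnitude)
  fit <- lm(magnitude ~ speed + I(speed^2), data = d)
  co <- coef(fit)
  if (anyNA(co)) stop("rank-deficient design", call. = FALSE)
  list(coefficients = setNames(as.numeric(co),
                               c("intercept", "linear", "quadratic")),
       fitted = unname(fit$fitted.values), model = fit)
}

#' Process a kinematic trial end to end
#'
#' Smooths each joint angle at 5 Hz, differentiates to velocity and
#' acceleration, averages over normalized cycles, and extracts the
#' windowed peak accelerations.
#'
#' @param trial A [synthesize_kinematics()] result, or a compatible list
#'   with `angle` (named list of vectors), `fs` and `heel_contacts`.
#' @param windows Peak windows (default [default_peak_windows()]).
#' @param smooth Apply the 5 Hz low-pass first (default `TRUE`).
#' @return List with per-joint `normalized` (angle/velocity/acceleration,
#'   100 bins each) and `peaks` (data frame).
#' @export
process_kinematics <- function(trial, windows = default_peak_windows(),
                               smooth = TRUE) {
  hc <- trial$heel_contacts
  normalized <- list()
  acc100 <- list()
  for (j in names(trial$angle)) {
    ang <- trial$angle[[j]]
    if (smooth) ang <- smooth_trajectory(ang, trial$fs)
    d <- differentiate(ang, trial$fs)
    normalized[[j]] <- list(
      angle = normalize_cycle_average(ang, hc),
      velocity = normalize_cycle_average(d$velocity, hc),
      acceleration = normalize_cycle_average(d$acceleration, hc))
    acc100[[j]] <- normalized[[j]]$acceleration
  }
  list(normalized = normalized,
       peaks = find_peak_accelerations(acc100, windows))
}
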