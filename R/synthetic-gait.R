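# Synthetic gait generator: ground-truth synergy structure, raw-like EMG,
# heel-contact events and joint kinematics, so every downstream stage has a
# known-answer test.

#' Ground-truth synergy structure for simulation
#'
#' Bundles a non-negative muscle weighting matrix (unit-norm columns) with
#' the parameters of each synergy's cycle-periodic activation waveform:
#' center of activation (% gait cycle at the reference speed), circular
#' width, amplitude, and a signed speed slope describing how the center of
#' activity drifts with walking speed (% gait cycle per km/h).
#'
#' @param weightings Non-negative numeric matrix, muscles x synergies, with
#'   unit Euclidean norm columns (see [make_weightings()]).
#' @param profile_centers Numeric, center of each activation bump in
#'   `[0, 100)` % gait cycle at `reference_speed`.
#' @param profile_widths Positive numeric, circular-Gaussian width of each
#'   bump in % gait cycle (approximately its standard deviation).
#' @param profile_amplitudes Non-negative numeric, peak value of each bump.
#' @param coa_slopes Numeric, signed center shift in % gait cycle per km/h;
#'   negative values move a synergy earlier as speed increases.
#' @param reference_speed Speed (km/h) at which `profile_centers` apply.
#' @return An object of class `gait_synergies`.
#' @seealso [default_ground_truth()], [synthesize_emg()]
#' @export
gait_synergies <- function(weightings, profile_centers, profile_widths,
                           profile_amplitudes, coa_slopes,
                           reference_speed = 4) {
  stop_if_not_matrix(weightings)
  stop_if_negative(weightings)
  n_syn <- ncol(weightings)
  norms <- col_norms(weightings)
  if (any(abs(norms - 1) > 1e-9)) {
    stop("weighting columns must have unit Euclidean norm", call. = FALSE)
  }
  for (arg in list(profile_centers, profile_widths, profile_amplitudes,
                   coa_slopes)) {
    if (length(arg) != n_syn) {
      stop("profile parameter lengths must equal the number of synergies",
           call. = FALSE)
    }
  }
  if (any(profile_centers < 0 | profile_centers >= 100)) {
    stop("profile_centers must lie in [0, 100)", call. = FALSE)
  }
  if (any(profile_widths <= 0)) {
    stop("profile_widths must be > 0", call. = FALSE)
  }
  stop_if_negative(profile_amplitudes)
  structure(
    list(weightings = weightings,
         profile_centers = as.numeric(profile_centers),
         profile_widths = as.numeric(profile_widths),
         profile_amplitudes = as.numeric(profile_amplitudes),
         coa_slopes = as.numeric(coa_slopes),
         reference_speed = reference_speed),
    class = "gait_synergies")
}

#' @export
print.gait_synergies <- function(x, ...) {
  cat(sprintf("Ground-truth synergies: %d muscles x %d synergies\n",
              nrow(x$weightings), ncol(x$weightings)))
  cat("  centers (% cycle):", paste(round(x$profile_centers, 1),
                                    collapse = ", "), "\n")
  cat("  CoA slopes (%/km/h):", paste(round(x$coa_slopes, 2),
                                      collapse = ", "), "\n")
  invisible(x)
}

#' Draw a random non-negative weighting matrix with distinguishable columns
#'
#' Columns are drawn from cubed uniforms (sparse-ish, as real muscle
#' weightings are) and scaled to unit Euclidean norm.  The whole matrix is
#' redrawn until every pairwise column cosine similarity is below
#' `max_similarity`, so the planted synergies are separable.
#'
#' @param n_muscles Number of muscles (rows).
#' @param n_synergies Number of synergies (columns); must not exceed
#'   `n_muscles`.
#' @param seed Integer seed; the result is a pure function of the arguments.
#' @param max_similarity Pairwise cosine similarity ceiling (default 0.9).
#' @param max_tries Redraw budget before giving up.
#' @return Non-negative `n_muscles` x `n_synergies` matrix with unit-norm
#'   columns.
#' @export
make_weightings <- function(n_muscles, n_synergies, seed,
                            max_similarity = 0.9, max_tries = 200L) {
  if (n_synergies > n_muscles) {
    stop("n_synergies must not exceed n_muscles", call. = FALSE)
  }
  if (n_synergies < 1L) stop("n_synergies must be >= 1", call. = FALSE)
  set.seed(as.integer(seed))
  for (try in seq_len(max_tries)) {
    w <- matrix(runif(n_muscles * n_synergies)^3, n_muscles, n_synergies)
    w <- pmax(w, 1e-6)
    w <- sweep(w, 2, col_norms(w), "/")
    if (n_synergies == 1L) return(w)
    sims <- crossprod(w)
    diag(sims) <- 0
    if (max(sims) < max_similarity) return(w)
  }
  stop(sprintf(
    "could not draw %d synergies with pairwise cosine < %.2f in %d tries",
    n_synergies, max_similarity, max_tries), call. = FALSE)
}

#' Circular-Gaussian activation waveforms on the 100-bin gait cycle
#'
#' Each synergy's activation is a von-Mises-shaped bump: periodic in the
#' gait cycle, so a burst centered near 0%/100% wraps continuously, and
#' exactly equal to its amplitude at the center.  `width` plays the role of
#' a circular standard deviation in % gait cycle.
#'
#' @param centers Bump centers in % gait cycle (values taken modulo 100).
#' @param widths Positive widths in % gait cycle.
#' @param amplitudes Non-negative peak values.
#' @param n_bins Bins per cycle (default 100).
#' @return Matrix, synergies x `n_bins`, rows are the waveforms.
#' @export
make_activation_profiles <- function(centers, widths, amplitudes,
                                     n_bins = 100L) {
  k <- length(centers)
  if (length(widths) != k || length(amplitudes) != k) {
    stop("centers, widths and amplitudes must have equal length",
         call. = FALSE)
  }
  if (any(widths <= 0)) stop("widths must be > 0", call. = FALSE)
  stop_if_negative(amplitudes)
  phi <- 2 * pi * seq_len(n_bins) / n_bins
  out <- matrix(0, k, n_bins)
  for (i in seq_len(k)) {
    phi0 <- 2 * pi * (centers[i] %% 100) / 100
    kappa <- (n_bins / (2 * pi * widths[i]))^2
    out[i, ] <- amplitudes[i] * exp(kappa * (cos(phi - phi0) - 1))
  }
  out
}

#' Shift activation centers with walking speed
#'
#' Applies the linear drift model
#' `center(speed) = wrap(center(ref) + slope * (speed - ref), 100)`,
#' which reproduces the observed behavior that support- and
#' swing-initiation synergies move earlier with speed while swing and
#' leg-deceleration synergies move later, and the propulsion synergy stays
#' put.
#'
#' @param gt A [gait_synergies()] object.
#' @param speed Walking speed, km/h.
#' @param reference_speed Reference speed; defaults to the one stored in
#'   `gt`.
#' @return Numeric vector of shifted centers in `[0, 100)`.
#' @export
shift_centers_for_speed <- function(gt, speed,
                                    reference_speed = gt$reference_speed) {
  (gt$profile_centers + gt$coa_slopes * (speed - reference_speed)) %% 100
}

#' Default five-synergy ground truth
#'
#' Mimics the canonical composition of walking synergies: loading
#' response/body support (VL, Gmed, Gmax), plantar-flexor propulsion (MG,
#' LG, SOL), swing initiation (RF, AL, ERE), swing (TA, RF, TFL) and
#' late-swing leg deceleration (TA, BF).  The support and swing-initiation
#' synergies drift earlier with speed, the swing-phase synergies later, and
#' propulsion is speed-invariant.
#'
#' @param n_synergies 4 or 5; with 4 the late-swing synergy is dropped.
#' @return A [gait_synergies()] object with named muscle rows.
#' @export
default_ground_truth <- function(n_synergies = 5L) {
  muscles <- default_muscles()
  loadings <- list(
    c(VL = 1, Gmed = 0.85, Gmax = 0.7, BF = 0.3),
    c(MG = 1, LG = 0.9, SOL = 0.95),
    c(RF = 0.9, AL = 1, ERE = 0.7),
    c(TA = 1, RF = 0.45, TFL = 0.6),
    c(TA = 1, BF = 0.5, ERE = 0.25))
  centers <- c(10, 45, 62, 75, 92)
  widths <- c(8, 7, 6, 7, 6)
  slopes <- c(-1.2, 0, -1.0, 1.0, 1.2)
  keep <- seq_len(n_synergies)
  w <- matrix(0.03, length(muscles), length(keep),
              dimnames = list(muscles, NULL))
  for (j in keep) w[names(loadings[[j]]), j] <- loadings[[j]]
  w <- sweep(w, 2, col_norms(w), "/")
  gait_synergies(w, centers[keep], widths[keep], rep(1, length(keep)),
                 slopes[keep])
}

#' Trial configuration for the synthetic generator
#'
#' @param speed Walking speed, km/h.
#' @param n_cycles Number of gait cycles to simulate (>= 40, so that 10 can
#'   be discarded and 30 analyzed).
#' @param cycle_duration_mean Mean cycle duration, seconds.  The default
#'   shortens with speed the way real stride times do.
#' @param cycle_duration_cv Coefficient of variation of cycle duration.
#' @param emg_fs EMG sampling rate, Hz.
#' @param kin_fs Kinematic sampling rate, Hz.
#' @param envelope_noise_sd Additive broadband noise on each raw channel,
#'   as a fraction of that channel's envelope peak.
#' @param carrier_band Band (Hz) of the EMG interference carrier.
#' @param angle_noise_sd Measurement noise on joint angles, degrees.
#' @param seed Integer seed.
#' @return An object of class `trial_config`.
#' @export
trial_config <- function(speed = 4, n_cycles = 45L,
                         cycle_duration_mean = NULL,
                         cycle_duration_cv = 0.03,
                         emg_fs = 1000, kin_fs = 100,
                         envelope_noise_sd = 0.05,
                         carrier_band = c(20, 450),
                         angle_noise_sd = 0, seed = 1L) {
  if (is.null(cycle_duration_mean)) {
    # stride time falls roughly linearly with treadmill speed
    cycle_duration_mean <- max(0.6, 1.45 - 0.08 * speed)
  }
  if (n_cycles < 40L) stop("n_cycles must be >= 40", call. = FALSE)
  if (cycle_duration_cv < 0) {
    stop("cycle_duration_cv must be >= 0", call. = FALSE)
  }
  if (emg_fs <= 2 * carrier_band[2]) {
    stop("emg_fs must exceed twice the upper carrier band edge",
         call. = FALSE)
  }
  structure(
    list(speed = speed, n_cycles = as.integer(n_cycles),
         cycle_duration_mean = cycle_duration_mean,
         cycle_duration_cv = cycle_duration_cv,
         emg_fs = emg_fs, kin_fs = kin_fs,
         envelope_noise_sd = envelope_noise_sd,
         carrier_band = carrier_band,
         angle_noise_sd = angle_noise_sd,
         seed = as.integer(seed)),
    class = "trial_config")
}

# Truncated-normal cycle durations, floored at 0.3 s so every cycle is
# physically plausible and long enough to resample.
draw_cycle_durations <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    out[need] <- rnorm(length(need), mean, cv * mean)
    need <- which(out < 0.3)
  }
  out
}

# Resample one 100-bin periodic waveform to n samples spanning one cycle.
# The waveform is treated as circular: bin 100 joins bin 1.
resample_cycle <- function(bins100, n) {
  nb <- length(bins100)
  x <- c(0, seq_len(nb)) / nb            # bin t sits at fraction t/nb
  y <- c(bins100[nb], bins100)           # wrap for continuity at 0
  xout <- (seq_len(n) - 1) / n
  approx(x, y, xout = xout)$y
}

#' Synthesize a raw-like multi-channel EMG recording
#'
#' Builds the envelope of each muscle as the non-negative mixture
#' `W %*% C(speed)` of the ground-truth weightings and speed-shifted
#' activation waveforms, resamples it to each cycle's own duration (drawn
#' from a truncated normal), and modulates a band-limited white-noise
#' carrier with it; broadband additive noise is scaled to
#' `envelope_noise_sd` times each channel's envelope peak.  Heel contacts
#' mark cycle starts.  The output is a pure function of `(gt, cfg)`.
#'
#' @param gt A [gait_synergies()] ground truth.
#' @param cfg A [trial_config()].
#' @return An object of class `emg_recording` with elements `signals`
#'   (channels x samples), `fs`, `muscle_labels`, `heel_contacts` (sample
#'   indices), `speed`; the noise-free envelope and per-cycle activations
#'   are attached as attributes `true_envelope` and `true_centers` for
#'   known-answer tests.
#' @export
synthesize_emg <- function(gt, cfg) {
  stopifnot(inherits(gt, "gait_synergies"), inherits(cfg, "trial_config"))
  set.seed(derive_seed(cfg$seed, "emg"))
  n_mus <- nrow(gt$weightings)
  centers <- shift_centers_for_speed(gt, cfg$speed)
  profiles <- make_activation_profiles(centers, gt$profile_widths,
                                       gt$profile_amplitudes)
  env100 <- gt$weightings %*% profiles          # muscles x 100

  # one extra partial cycle so the final delimiting heel contact falls
  # inside the record, as it would with a real foot switch
  n_full <- cfg$n_cycles
  durations <- draw_cycle_durations(n_full + 1L, cfg$cycle_duration_mean,
                                    cfg$cycle_duration_cv)
  n_per_cycle <- pmax(50L, as.integer(round(durations * cfg$emg_fs)))
  tail_n <- max(10L, as.integer(round(0.2 * n_per_cycle[n_full + 1L])))
  total <- sum(n_per_cycle[seq_len(n_full)]) + tail_n
  heel <- as.integer(cumsum(c(1L, n_per_cycle[seq_len(n_full)])))

  envelope <- matrix(0, n_mus, total)
  pos <- 1L
  for (k in seq_len(n_full + 1L)) {
    n <- n_per_cycle[k]
    cyc <- matrix(0, n_mus, n)
    for (m in seq_len(n_mus)) {
      cyc[m, ] <- resample_cycle(env100[m, ], n)
    }
    keep <- min(n, total - pos + 1L)
    if (keep <= 0L) break
    envelope[, pos:(pos + keep - 1L)] <- cyc[, seq_len(keep), drop = FALSE]
    pos <- pos + keep
  }

  ny <- cfg$emg_fs / 2
  bf <- signal::butter(4, cfg$carrier_band / ny, type = "pass")
  signals <- matrix(0, n_mus, total)
  for (m in seq_len(n_mus)) {
    carrier <- signal::filter(bf, rnorm(total))
    carrier <- carrier / sd(carrier)
    noise_sd <- cfg$envelope_noise_sd * max(envelope[m, ])
    signals[m, ] <- carrier * envelope[m, ] + rnorm(total, sd = noise_sd)
  }
  rownames(signals) <- rownames(envelope) <-
    if (!is.null(rownames(gt$weightings))) rownames(gt$weightings)
    else default_muscles()[seq_len(n_mus)]

  rec <- emg_recording(signals, cfg$emg_fs, rownames(signals), heel,
                       cfg$speed)
  attr(rec, "true_envelope") <- envelope
  attr(rec, "true_centers") <- centers
  attr(rec, "ground_truth") <- gt
  rec
}

#' Multi-channel EMG recording container
#'
#' @param signals Numeric matrix, channels x samples.
#' @param fs Sampling rate, Hz.
#' @param muscle_labels One name per channel.
#' @param heel_contacts Strictly increasing sample indices of successive
#'   right heel contacts.
#' @param speed Walking speed label, km/h.
#' @return An object of class `emg_recording`.
#' @export
emg_recording <- function(signals, fs, muscle_labels, heel_contacts,
                          speed = NA_real_) {
  stop_if_not_matrix(signals)
  if (length(muscle_labels) != nrow(signals)) {
    stop("muscle_labels length must equal the channel count", call. = FALSE)
  }
  heel_contacts <- as.integer(heel_contacts)
  if (any(diff(heel_contacts) <= 0)) {
    stop("heel_contacts must be strictly increasing", call. = FALSE)
  }
  structure(
    list(signals = signals, fs = fs,
         muscle_labels = as.character(muscle_labels),
         heel_contacts = heel_contacts, speed = speed),
    class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf(
    "EMG recording: %d channels, %.1f s at %g Hz, %d heel contacts, %s km/h\n",
    nrow(x$signals), ncol(x$signals) / x$fs, x$fs,
    length(x$heel_contacts), format(x$speed)))
  invisible(x)
}

# Harmonic coefficient tables for the three sagittal joints.  Amplitudes
# (deg) are scaled up with speed; phases are fixed so trajectories have the
# usual single dominant flexion/extension excursion per cycle.
kin_harmonics <- function(speed) {
  scale <- 0.55 + 0.09 * speed
  list(
    ankle = list(a0 = 2,
                 amp = c(8, 5, 2, 0.8) * scale,
                 phase = c(0.4, 2.4, 1.1, 0.3)),
    knee = list(a0 = 25,
                amp = c(24, 12, 3.5, 1.2) * scale,
                phase = c(-1.9, 0.9, 0.2, 1.4)),
    hip = list(a0 = 10,
               amp = c(18, 3.5, 1.2, 0.4) * scale,
               phase = c(1.2, 0.5, 1.8, 0.7)))
}

#' Synthesize smooth joint-angle trajectories
#'
#' Each joint angle is a sum of four harmonics of the gait cycle whose
#' amplitudes grow monotonically with speed; the closed-form first and
#' second derivatives are stored alongside so numerical differentiation can
#' be tested against an analytic oracle.  Angles are in degrees with 0 at
#' the anatomical position.
#'
#' @param cfg A [trial_config()].
#' @param speed Walking speed, km/h; defaults to `cfg$speed`.
#' @return An object of class `kinematic_trial`: per-joint angle vectors at
#'   `cfg$kin_fs`, heel-contact sample indices, and attribute
#'   `analytic` holding velocity/acceleration closed forms.
#' @export
synthesize_kinematics <- function(cfg, speed = cfg$speed) {
  stopifnot(inherits(cfg, "trial_config"))
  set.seed(derive_seed(cfg$seed, "kin"))
  T_cyc <- cfg$cycle_duration_mean
  n_per <- as.integer(round(T_cyc * cfg$kin_fs))
  total <- n_per * cfg$n_cycles
  t <- (seq_len(total) - 1) / cfg$kin_fs
  hs <- kin_harmonics(speed)
  ang <- vel <- acc <- list()
  for (j in names(hs)) {
    h <- hs[[j]]
    a <- rep(h$a0, total); v <- numeric(total); ac <- numeric(total)
    for (k in seq_along(h$amp)) {
      w <- 2 * pi * k / T_cyc
      a <- a + h$amp[k] * sin(w * t + h$phase[k])
      v <- v + h$amp[k] * w * cos(w * t + h$phase[k])
      ac <- ac - h$amp[k] * w^2 * sin(w * t + h$phase[k])
    }
    if (cfg$angle_noise_sd > 0) {
      a <- a + rnorm(total, sd = cfg$angle_noise_sd)
    }
    ang[[j]] <- a; vel[[j]] <- v; acc[[j]] <- ac
  }
  structure(
    list(angle = ang, fs = cfg$kin_fs,
         heel_contacts = as.integer(seq(1L, total + 1L, by = n_per)),
         speed = speed, cycle_duration = T_cyc),
    analytic = list(velocity = vel, acceleration = acc),
    class = "kinematic_trial")
}
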