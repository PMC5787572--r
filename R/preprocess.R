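# EMG preprocessing: heel-contact segmentation, envelope extraction,
# 100-point time normalization, and the peak/unit-variance normalization
# applied before factorization.

#' Segment a recording into analyzed gait cycles
#'
#' One gait cycle runs from a right heel contact to the moment before the
#' next one.  The first `n_discard` cycles are dropped (gait is not yet
#' steady) and the following `n_keep` are analyzed.
#'
#' @param rec An [emg_recording()].
#' @param n_discard Initial cycles to exclude (default 10).
#' @param n_keep Cycles to analyze (default 30).
#' @return List of `n_keep` integer pairs `c(start, end)`, half-open spans
#'   `[start, end)` in sample indices, in temporal order.
#' @export
segment_cycles <- function(rec, n_discard = 10L, n_keep = 30L) {
  hc <- rec$heel_contacts
  need <- n_discard + n_keep + 1L
  if (length(hc) < need) {
    stop(sprintf(
      "need at least %d heel contacts (%d full cycles after discarding %d); got %d",
      need, n_keep, n_discard, length(hc)), call. = FALSE)
  }
  lapply(seq_len(n_keep), function(k) {
    c(start = hc[n_discard + k], end = hc[n_discard + k + 1L])
  })
}

# Zero-phase Butterworth of given order/type via forward-backward
# filtering.  The signal is extended by odd reflection at both ends before
# filtering so startup transients decay inside the padding, not the data.
zero_phase_filter <- function(x, fs, cutoff, type, order = 4L) {
  bf <- signal::butter(order, cutoff[1] / (fs / 2), type = type)
  n <- length(x)
  npad <- min(n - 1L, as.integer(ceiling(6 * fs / cutoff[1])))
  pre <- 2 * x[1] - x[(npad + 1L):2]
  post <- 2 * x[n] - x[(n - 1L):(n - npad)]
  y <- as.numeric(signal::filtfilt(bf, c(pre, x, post)))
  y[(npad + 1L):(npad + n)]
}

#' EMG envelope: high-pass, rectify, low-pass
#'
#' Applies a zero-phase 4th-order Butterworth high-pass at `high_cut` Hz,
#' full-wave rectification, then a zero-phase 4th-order Butterworth
#' low-pass at `low_cut` Hz.  Zero-phase filtering preserves burst timing,
#' which the center-of-activity statistic depends on.  Tiny negative
#' low-pass ringing is clipped to zero.
#'
#' @param signals Numeric matrix, channels x samples (a single channel may
#'   be given as a vector).
#' @param fs Sampling rate, Hz (> 100).
#' @param high_cut High-pass cutoff, Hz (default 40).
#' @param low_cut Low-pass cutoff, Hz (default 10).
#' @return Non-negative envelope matrix, channels x samples.
#' @export
emg_envelope <- function(signals, fs, high_cut = 40, low_cut = 10) {
  if (is.vector(signals)) signals <- matrix(signals, nrow = 1L)
  stop_if_not_matrix(signals)
  if (fs <= 100) stop("fs must exceed 100 Hz", call. = FALSE)
  out <- signals
  for (m in seq_len(nrow(signals))) {
    x <- zero_phase_filter(signals[m, ], fs, high_cut, "high")
    x <- abs(x)
    x <- zero_phase_filter(x, fs, low_cut, "low")
    out[m, ] <- pmax(x, 0)
  }
  out
}

#' Time-normalize cycles to a fixed number of points
#'
#' Each cycle span is linearly interpolated over its own duration to
#' exactly `n_bins` points; cycles are concatenated in temporal order.
#'
#' @param envelope Channels x samples matrix.
#' @param spans List of half-open `c(start, end)` spans from
#'   [segment_cycles()].
#' @param n_bins Points per cycle (default 100).
#' @return Channels x (`n_bins` * cycles) matrix.
#' @export
time_normalize <- function(envelope, spans, n_bins = 100L) {
  if (is.vector(envelope)) envelope <- matrix(envelope, nrow = 1L)
  stop_if_not_matrix(envelope)
  n_cyc <- length(spans)
  out <- matrix(0, nrow(envelope), n_bins * n_cyc)
  rownames(out) <- rownames(envelope)
  for (k in seq_len(n_cyc)) {
    s <- spans[[k]]
    if (s[2] > ncol(envelope) + 1L || s[1] < 1L) {
      stop("cycle span outside the signal", call. = FALSE)
    }
    idx <- s[1]:(s[2] - 1L)
    if (length(idx) < 2L) {
      stop("cycle span shorter than 2 samples", call. = FALSE)
    }
    xout <- seq(1, length(idx), length.out = n_bins)
    cols <- (k - 1L) * n_bins + seq_len(n_bins)
    for (m in seq_len(nrow(envelope))) {
      out[m, cols] <- approx(seq_along(idx), envelope[m, idx],
                             xout = xout)$y
    }
  }
  out
}

#' Gait-cycle envelope matrix container
#'
#' The muscles x (100 bins x cycles) non-negative matrix consumed by the
#' factorization, together with the per-muscle normalization factors.
#'
#' @param values Non-negative numeric matrix with `n_bins * n_cycles`
#'   columns.
#' @param n_cycles Number of concatenated cycles.
#' @param speed Walking speed label, km/h.
#' @param normalization_record List with per-muscle `peak` and `sd`, or
#'   `NULL` before normalization.
#' @param n_bins Bins per cycle (default 100).
#' @return An object of class `cycle_matrix`.
#' @export
cycle_matrix <- function(values, n_cycles, speed = NA_real_,
                         normalization_record = NULL, n_bins = 100L) {
  stop_if_not_matrix(values)
  stop_if_negative(values)
  if (ncol(values) != n_bins * n_cycles) {
    stop("column count must equal n_bins * n_cycles", call. = FALSE)
  }
  structure(
    list(values = values, n_cycles = as.integer(n_cycles),
         n_bins = as.integer(n_bins), speed = speed,
         normalization_record = normalization_record),
    class = "cycle_matrix")
}

#' @export
print.cycle_matrix <- function(x, ...) {
  cat(sprintf("Cycle matrix: %d muscles x %d bins x %d cycles (%s)\n",
              nrow(x$values), x$n_bins, x$n_cycles,
              if (is.null(x$normalization_record)) "unnormalized"
              else "unit-variance normalized"))
  invisible(x)
}

#' @export
as.matrix.cycle_matrix <- function(x, ...) x$values

#' Peak and unit-variance normalization before factorization
#'
#' Each muscle row is divided by its peak over the analyzed data and then
#' by its standard deviation, so every muscle contributes unit variance to
#' the factorization.  The factors are stored in `normalization_record`
#' for inverse mapping.  The operation is idempotent.
#'
#' @param cm A [cycle_matrix()] (or plain matrix plus `n_cycles`).
#' @param n_cycles Needed only when `cm` is a plain matrix.
#' @return A normalized [cycle_matrix()].
#' @export
normalize_for_nmf <- function(cm, n_cycles = NULL) {
  if (!inherits(cm, "cycle_matrix")) {
    if (is.null(n_cycles)) {
      stop("n_cycles is required when passing a plain matrix",
           call. = FALSE)
    }
    cm <- cycle_matrix(cm, n_cycles)
  }
  v <- cm$values
  labels <- rownames(v)
  if (is.null(labels)) labels <- paste0("m", seq_len(nrow(v)))
  peaks <- apply(v, 1, max)
  zero_rows <- which(peaks <= 0)
  if (length(zero_rows)) {
    stop(sprintf("all-zero muscle row(s): %s",
                 paste(labels[zero_rows], collapse = ", ")), call. = FALSE)
  }
  v <- v / peaks
  sds <- apply(v, 1, sd)
  flat <- which(sds <= 1e-12)
  if (length(flat)) {
    stop(sprintf("zero-variance muscle row(s): %s",
                 paste(labels[flat], collapse = ", ")), call. = FALSE)
  }
  v <- v / sds
  names(peaks) <- names(sds) <- labels
  cycle_matrix(v, cm$n_cycles, cm$speed,
               normalization_record = list(peak = peaks, sd = sds),
               n_bins = cm$n_bins)
}

#' Map weightings back to raw envelope units
#'
#' Extraction runs on the peak/unit-variance-normalized matrix, so a
#' fitted weighting vector lives in normalized space: each muscle's entry
#' is scaled by `1 / (peak * sd)`.  This inverts that scaling (and
#' rescales columns to unit norm), which is needed before comparing
#' weightings to quantities expressed in raw envelope units.
#'
#' @param W Weighting matrix fitted on a normalized [cycle_matrix()].
#' @param normalization_record The matrix's `normalization_record`.
#' @return Weighting matrix in raw envelope units, unit-norm columns.
#' @export
denormalize_weightings <- function(W, normalization_record) {
  f <- normalization_record$peak * normalization_record$sd
  if (length(f) != nrow(W)) {
    stop("normalization record does not match the weighting rows",
         call. = FALSE)
  }
  W_raw <- W * f
  sweep(W_raw, 2, col_norms(W_raw), "/")
}

#' Full preprocessing chain for one recording
#'
#' [segment_cycles()] then [emg_envelope()] then [time_normalize()] then
#' [normalize_for_nmf()].
#'
#' @param rec An [emg_recording()].
#' @inheritParams segment_cycles
#' @inheritParams emg_envelope
#' @param n_bins Points per cycle (default 100).
#' @return A normalized [cycle_matrix()].
#' @export
preprocess_recording <- function(rec, n_discard = 10L, n_keep = 30L,
                                 high_cut = 40, low_cut = 10,
                                 n_bins = 100L) {
  spans <- segment_cycles(rec, n_discard, n_keep)
  env <- emg_envelope(rec$signals, rec$fs, high_cut, low_cut)
  vals <- time_normalize(env, spans, n_bins)
  rownames(vals) <- rec$muscle_labels
  normalize_for_nmf(cycle_matrix(vals, n_keep, rec$speed, n_bins = n_bins))
}
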