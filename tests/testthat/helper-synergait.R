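# Shared fixture builders: everything is generated in code at test time.

# Noise-free envelope cycle matrix built directly from a planted
# factorization (the exact-rank construction): W (unit-norm columns) times
# circular-Gaussian activation waveforms, tiled over n_cycles.
planted_cycle_matrix <- function(n_synergies = 4L, n_cycles = 30L,
                                 seed = 42L, centers = NULL, widths = NULL,
                                 normalize = TRUE) {
  w <- make_weightings(12L, n_synergies, seed = seed)
  if (is.null(centers)) {
    centers <- seq(5, 95, length.out = n_synergies)
  }
  if (is.null(widths)) widths <- rep(7, n_synergies)
  prof <- make_activation_profiles(centers, widths, rep(1, n_synergies))
  M <- w %*% prof
  rownames(M) <- default_muscles()
  M_tiled <- M[, rep(seq_len(100L), n_cycles)]
  cm <- if (normalize) {
    normalize_for_nmf(M_tiled, n_cycles = n_cycles)
  } else {
    cycle_matrix(M_tiled, n_cycles)
  }
  list(cm = cm, W = w, profiles = prof, centers = centers)
}

# A single activation bump (length 100) with all mass at one bin.
delta_profile <- function(bin, n_bins = 100L) {
  act <- numeric(n_bins)
  act[bin] <- 1
  act
}

# Alternating nonnegative least squares via pracma::lsqnonneg: an
# independent reference factorization used only as a cross-check oracle.
anls_reference <- function(M, N, seed = 1L, n_iter = 60L) {
  set.seed(seed)
  W <- matrix(runif(nrow(M) * N) + 0.1, nrow(M), N)
  C <- matrix(0, N, ncol(M))
  for (it in seq_len(n_iter)) {
    for (j in seq_len(ncol(M))) {
      C[, j] <- pracma::lsqnonneg(W, M[, j])$x
    }
    for (i in seq_len(nrow(M))) {
      W[i, ] <- pracma::lsqnonneg(t(C), M[i, ])$x
    }
  }
  list(W = W, C = C, sse = sum((M - W %*% C)^2))
}
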