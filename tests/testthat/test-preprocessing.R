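make_rec_with_contacts <- function(n_contacts, cycle_len = 500L) {
  n <- n_contacts * cycle_len + 100L
  sig <- matrix(rnorm(2 * n), 2L)
  emg_recording(sig, 1000, c("a", "b"),
                seq(1L, by = cycle_len, length.out = n_contacts))
}

test_that("cycle segmentation discards the first 10 cycles and keeps 30", {
  rec <- make_rec_with_contacts(45L)
  spans <- segment_cycles(rec)
  expect_length(spans, 30L)
  hc <- rec$heel_contacts
  expect_equal(unname(spans[[1]]), c(hc[11], hc[12]))
  expect_equal(unname(spans[[30]]), c(hc[40], hc[41]))
  # spans tile the analyzed record without gaps
  starts <- vapply(spans, `[`, integer(1), 1L)
  ends <- vapply(spans, `[`, integer(1), 2L)
  expect_equal(starts[-1], ends[-30])

  expect_length(segment_cycles(make_rec_with_contacts(41L)), 30L)
  expect_error(segment_cycles(make_rec_with_contacts(40L)), "41")
})

test_that("envelope extraction removes DC and recovers a rectified-sine mean", {
  fs <- 1000
  n <- 4000L
  # constant input is killed by the 40 Hz high-pass
  dc <- emg_envelope(rep(2, n), fs)
  expect_lt(max(abs(dc)), 1e-6)

  # amplitude-a sinusoid at 100 Hz: envelope ~ mean |a sin| = 2a/pi, flat
  a <- 1.7
  x <- a * sin(2 * pi * 100 * (1:n) / fs)
  env <- emg_envelope(x, fs)[1, 500:3500]
  expect_equal(mean(env), 2 * a / pi, tolerance = 0.05)
  expect_lt(sd(env) / mean(env), 0.05)

  expect_error(emg_envelope(c(1, NA, 3), 1000), "non-finite")
  expect_error(emg_envelope(rep(1, 100), 50), "fs")
})

test_that("time normalization yields 100 points per cycle and is exact on ramps", {
  env <- matrix(seq(0, 1, length.out = 1000L), 1L)
  out <- time_normalize(env, list(c(1L, 1001L)))
  expect_length(out[1, ], 100L)
  # linear interpolation keeps a linear ramp linear
  expect_equal(diff(out[1, ]), rep(diff(out[1, ])[1], 99L),
               tolerance = 1e-12)

  two <- time_normalize(rbind(c(1:10, 21:40) / 40),
                        list(c(1L, 11L), c(11L, 31L)))
  expect_equal(ncol(two), 200L)
  expect_lt(max(two[1, 1:100]), min(two[1, 101:200]))

  expect_error(time_normalize(env, list(c(5L, 6L))), "2 samples")
})

test_that("peak/unit-variance normalization has its stated invariants", {
  set.seed(1)
  vals <- matrix(abs(rnorm(12 * 300)), 12L,
                 dimnames = list(default_muscles(), NULL))
  cm <- normalize_for_nmf(vals, n_cycles = 3L)
  expect_true(all(cm$values >= 0))
  expect_equal(unname(apply(cm$values, 1, var)), rep(1, 12L),
               tolerance = 1e-6)
  # input scale drops out
  cm10 <- normalize_for_nmf(vals * 10, n_cycles = 3L)
  expect_equal(cm$values, cm10$values, tolerance = 1e-12)
  # idempotent
  cm2 <- normalize_for_nmf(cm)
  expect_equal(cm$values, cm2$values, tolerance = 1e-9)
  expect_named(cm$normalization_record, c("peak", "sd"))

  flat <- vals
  flat[3, ] <- 5
  expect_error(normalize_for_nmf(flat, n_cycles = 3L), "SOL")
  zero <- vals
  zero[7, ] <- 0
  expect_error(normalize_for_nmf(zero, n_cycles = 3L), "BF")
})

test_that("denormalization undoes the per-muscle scaling of weightings", {
  fix <- planted_cycle_matrix(3L, n_cycles = 6L, seed = 5L)
  dec <- fit_nmf(fix$cm, 3L, n_restarts = 10L, seed = 1L)
  w_raw <- denormalize_weightings(dec$W, fix$cm$normalization_record)
  sims <- vapply(seq_len(3L), function(j) {
    max(vapply(seq_len(3L), function(k) {
      cosine_sim(w_raw[, j], fix$W[, k])
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(sims > 0.99))
  expect_error(denormalize_weightings(dec$W[1:5, ],
                                      fix$cm$normalization_record),
               "does not match")
})

test_that("preprocessed synthetic data tracks the planted envelope per muscle", {
  gt <- default_ground_truth(4)
  cfg <- trial_config(speed = 4, n_cycles = 42L, envelope_noise_sd = 0.05,
                      seed = 3L)
  rec <- synthesize_emg(gt, cfg)
  cm <- preprocess_recording(rec)
  expect_equal(dim(cm$values), c(12L, 3000L))
  prof <- make_activation_profiles(attr(rec, "true_centers"),
                                   gt$profile_widths,
                                   gt$profile_amplitudes)
  target <- (gt$weightings %*% prof)[, rep(1:100, 30L)]
  r <- vapply(seq_len(12L), function(m) cor(cm$values[m, ], target[m, ]),
              numeric(1))
  expect_gt(median(r), 0.9)
})
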