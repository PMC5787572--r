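test_that("random weightings are unit-norm, non-negative, distinguishable and seeded", {
  for (n_syn in c(1L, 4L, 5L)) {
    w <- make_weightings(12L, n_syn, seed = 1L)
    expect_equal(dim(w), c(12L, n_syn))
    expect_true(all(w >= 0))
    expect_equal(unname(sqrt(colSums(w^2))), rep(1, n_syn),
                 tolerance = 1e-9)
    if (n_syn > 1L) {
      sims <- crossprod(w)
      diag(sims) <- 0
      expect_lt(max(sims), 0.9)
    }
  }
  expect_identical(make_weightings(12L, 4L, seed = 1L),
                   make_weightings(12L, 4L, seed = 1L))
  expect_false(identical(make_weightings(12L, 4L, seed = 1L),
                         make_weightings(12L, 4L, seed = 2L)))
  expect_error(make_weightings(12L, 13L, seed = 1L), "exceed")
  # impossible separation: many synergies forced below a tiny similarity
  expect_error(make_weightings(3L, 3L, seed = 1L, max_similarity = 0.01,
                               max_tries = 5L), "could not draw")
})

test_that("activation profiles are circular bumps with the stated center and peak", {
  p <- make_activation_profiles(50, 8, 2)
  expect_equal(length(p[1, ]), 100L)
  expect_true(all(p >= 0))
  expect_equal(max(p), 2, tolerance = 1e-9)
  expect_equal(which.max(p[1, ]), 50L)
  # symmetric about bin 50, so its CoA sits at 180 degrees
  expect_equal(center_of_activity(p[1, ])$coa_deg, 180, tolerance = 1e-6)

  # a wide bump near the cycle end wraps onto the start
  pw <- make_activation_profiles(98, 10, 1)[1, ]
  expect_gt(pw[5], 0.5)
  expect_gt(pw[95], 0.5)

  expect_equal(make_activation_profiles(30, 5, 0)[1, ], rep(0, 100))
  expect_error(make_activation_profiles(30, 0, 1), "widths")
  expect_error(make_activation_profiles(c(10, 20), 5, 1), "equal length")
})

test_that("speed shifts centers linearly with wraparound", {
  w <- make_weightings(12L, 3L, seed = 3L)
  gt <- gait_synergies(w, c(10, 50, 99), c(5, 5, 5), c(1, 1, 1),
                       c(-1, 0, 1), reference_speed = 4)
  expect_equal(shift_centers_for_speed(gt, 8)[2], 50)   # zero slope
  expect_equal(shift_centers_for_speed(gt, 8)[1], 6)    # -1 %/km/h
  expect_equal(shift_centers_for_speed(gt, 6)[3], 1)    # wraps past 100
  expect_equal(shift_centers_for_speed(gt, 4), c(10, 50, 99))
})

test_that("generated CoA matches the programmed center within one bin", {
  for (center in c(5, 25, 50, 75, 98)) {
    for (width in c(3, 8, 15)) {
      act <- make_activation_profiles(center, width, 1)[1, ]
      coa <- center_of_activity(act)$coa_pct
      d <- min(abs(coa - center), 100 - abs(coa - center))
      expect_lt(d, 1)
    }
  }
})

test_that("synthetic EMG has the configured cycle structure and is seed-reproducible", {
  gt <- default_ground_truth(4)
  cfg <- trial_config(speed = 4, n_cycles = 45L, seed = 9L)
  rec <- synthesize_emg(gt, cfg)
  expect_s3_class(rec, "emg_recording")
  expect_equal(nrow(rec$signals), 12L)
  # 45 heel-contact-delimited cycles need 46 contacts
  expect_equal(length(rec$heel_contacts), 46L)
  expect_true(all(diff(rec$heel_contacts) > 0))
  expect_lte(max(rec$heel_contacts), ncol(rec$signals))

  rec2 <- synthesize_emg(gt, cfg)
  expect_identical(rec$signals, rec2$signals)
  expect_identical(rec$heel_contacts, rec2$heel_contacts)
})

test_that("recovered envelope correlates with the generator's stored envelope", {
  gt <- default_ground_truth(4)
  cfg <- trial_config(speed = 4, n_cycles = 40L, envelope_noise_sd = 0,
                      seed = 21L)
  rec <- synthesize_emg(gt, cfg)
  env_hat <- emg_envelope(rec$signals, rec$fs)
  env_true <- attr(rec, "true_envelope")
  r <- vapply(seq_len(12L), function(m) {
    cor(env_hat[m, ], env_true[m, ])
  }, numeric(1))
  expect_gt(median(r), 0.95)
  expect_true(all(r > 0.9))
})

test_that("synthetic kinematics obey their analytic derivatives and speed scaling", {
  cfg <- trial_config(speed = 4, n_cycles = 40L, seed = 2L)
  kin <- synthesize_kinematics(cfg)
  expect_named(kin$angle, c("ankle", "knee", "hip"))
  ana <- attr(kin, "analytic")

  # numerical differentiation of the noise-free trajectory matches the
  # closed form away from the endpoints
  d <- differentiate(kin$angle$knee, kin$fs)
  mid <- 50:(length(d$velocity) - 50L)
  expect_lt(max(abs(d$velocity[mid] - ana$velocity$knee[mid])) /
              max(abs(ana$velocity$knee)), 0.02)
  expect_lt(max(abs(d$acceleration[mid] - ana$acceleration$knee[mid])) /
              max(abs(ana$acceleration$knee)), 0.02)

  # identical seed, identical trajectories
  expect_identical(kin$angle, synthesize_kinematics(cfg)$angle)

  # faster walking never reduces the peak analytic acceleration
  peak_acc <- function(speed) {
    k <- synthesize_kinematics(trial_config(speed = speed,
                                            n_cycles = 40L, seed = 2L))
    max(abs(attr(k, "analytic")$acceleration$hip))
  }
  speeds <- c(2, 4, 6, 8)
  peaks <- vapply(speeds, peak_acc, numeric(1))
  expect_true(all(diff(peaks) >= 0))
})
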