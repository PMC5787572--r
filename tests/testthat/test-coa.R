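test_that("center of activity handles point masses, symmetry and degeneracy", {
  d25 <- center_of_activity(delta_profile(25))
  expect_equal(d25$coa_deg, 90)
  expect_equal(d25$coa_pct, 25)
  expect_equal(d25$resultant_length, 1)

  # symmetric about bin 50
  act <- delta_profile(40) + delta_profile(60)
  expect_equal(center_of_activity(act)$coa_deg, 180, tolerance = 1e-9)

  expect_error(center_of_activity(rep(0, 100)), "all-zero")
  expect_error(center_of_activity(rep(1, 100)), "zero resultant")
  expect_error(center_of_activity(c(1, NA)), "non-finite")
  expect_error(center_of_activity(c(1, -1)), "non-negative")
})

test_that("CoA is scale invariant and rotation equivariant", {
  set.seed(5)
  act <- runif(100)^2
  base <- center_of_activity(act)$coa_pct
  expect_equal(center_of_activity(act * 37.5)$coa_pct, base,
               tolerance = 1e-12)
  for (s in c(1L, 13L, 50L, 99L)) {
    shifted <- act[((seq_len(100L) - 1L - s) %% 100L) + 1L]
    expect_equal(center_of_activity(shifted)$coa_pct,
                 (base + s) %% 100, tolerance = 1e-9)
  }
})

test_that("CoA equals the Monte-Carlo circular mean of act-weighted bins", {
  set.seed(9)
  for (i in 1:5) {
    # burst-like random profiles: a bump at a random phase over a noise
    # floor, the shape real activations take
    act <- make_activation_profiles(runif(1, 0, 100), runif(1, 4, 15),
                                    1)[1, ] + runif(100, 0, 0.2)
    est <- center_of_activity(act)
    draws <- as.vector(stats::rmultinom(1, 1e6, prob = act / sum(act)))
    theta <- seq_len(100) * 3.6
    mc <- circular_mean(rep(theta, draws))$mean_deg
    d <- abs(est$coa_deg - mc)
    expect_lt(min(d, 360 - d), 0.5)
  }
})

test_that("circular mean averages on the circle, not the line", {
  expect_equal(circular_mean(c(350, 10))$mean_deg, 0, tolerance = 1e-9)
  expect_equal(circular_mean(90)$mean_deg, 90)
  expect_equal(circular_mean(c(0, 90))$mean_deg, 45)
  expect_error(circular_mean(c(0, 180)), "zero resultant")
  expect_error(circular_mean(numeric(0)), "empty")
})

test_that("unwrapping makes wrap-straddling clusters contiguous", {
  x <- c(352.8, 356.4, 3.6, 7.2)   # 98%, 99%, 1%, 2% of the cycle
  u <- unwrap_angles(x)
  expect_lt(max(u) - min(u), 20)
  p <- unwrap_angles(c(98, 99, 1, 2), period = 100)
  expect_lt(max(p) - min(p), 5)
})

test_that("speed comparison detects programmed CoA drift and not a null", {
  speeds <- rep(c(2, 4, 6, 8), each = 8)
  # identical CoA distributions at every speed: nothing to detect
  set.seed(17)
  base <- rep(rnorm(8, 180, 4), times = 4)
  null_res <- compare_coa_across_speeds(base, speeds)
  expect_gt(null_res$p_value, 0.9)
  expect_false(any(null_res$tukey$significant))

  # drift of -1 % gait cycle per km/h (3.6 deg/km/h), subject SD 1%
  set.seed(18)
  drift <- 180 - 3.6 * (speeds - 4) + rnorm(length(speeds), 0, 3.6)
  res <- compare_coa_across_speeds(drift, speeds)
  expect_lt(res$p_value, 0.05)
  extreme <- res$tukey[res$tukey$pair %in% c("8-2", "2-8"), ]
  expect_true(extreme$significant)

  expect_error(compare_coa_across_speeds(drift[1:8], speeds[1:8]),
               "two speed conditions")
  expect_error(compare_coa_across_speeds(c(1, 2, 3), c(2, 4, 4)),
               "at least two CoA")
})

test_that("Tukey-Kramer intervals match the studentized-range closed form", {
  set.seed(19)
  k <- 3L; n <- 6L
  y <- rnorm(k * n, rep(c(0, 5, 10), each = n), 2) + 180
  g <- rep(c(2, 5, 8), each = n)
  res <- compare_coa_across_speeds(y, g, unwrap = FALSE)
  df <- k * n - k
  mse <- res$anova[["Mean Sq"]][2]
  half <- qtukey(0.95, k, df) / sqrt(2) * sqrt(mse * 2 / n)
  got <- res$tukey[res$tukey$pair == "5-2", ]
  means <- tapply(y, g, mean)
  expect_equal(got$diff, unname(means["5"] - means["2"]), tolerance = 1e-9)
  expect_equal(got$upr - got$diff, half, tolerance = 1e-9)
  expect_equal(got$diff - got$lwr, half, tolerance = 1e-9)
})

test_that("two-sample CoA comparison is wrap-safe and matches closed-form t", {
  a <- c(36, 39.6, 36, 39.6, 38, 37, 36.5, 38.5, 37.2, 36.8)
  expect_equal(compare_two_coa(a, a)$t, 0)
  expect_equal(compare_two_coa(a, a)$p_value, 1)

  set.seed(23)
  g1 <- 3.6 * rnorm(10, 10, 1)   # 10 +/- 1 % of the cycle, in degrees
  g2 <- 3.6 * rnorm(10, 40, 1)
  res <- compare_two_coa(g1, g2)
  expect_lt(res$p_value, 0.01)
  sp <- sqrt(((9) * var(g1) + (9) * var(g2)) / 18)
  t_hand <- (mean(g1) - mean(g2)) / (sp * sqrt(1 / 10 + 1 / 10))
  expect_equal(res$t, t_hand, tolerance = 1e-9)

  # clusters straddling the wrap point differ by ~4% of the cycle, not 96%
  set.seed(24)
  w1 <- (3.6 * rnorm(10, 98, 0.3)) %% 360
  w2 <- 3.6 * rnorm(10, 2, 0.3)
  wres <- compare_two_coa(w1, w2)
  expect_lt(abs(wres$mean_diff_deg), 30)

  expect_error(compare_two_coa(c(180, 180), c(90, 90)), "degenerate")
  expect_error(compare_two_coa(1, c(2, 3)), "at least two")
})
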