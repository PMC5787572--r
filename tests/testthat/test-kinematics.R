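test_that("5 Hz smoothing passes slow components and rejects fast ones", {
  fs <- 100
  t <- (0:999) / fs
  expect_equal(smooth_trajectory(rep(3, 1000), fs), rep(3, 1000),
               tolerance = 1e-6)
  slow <- sin(2 * pi * 1 * t)
  mid <- 200:800
  expect_lt(max(abs(smooth_trajectory(slow, fs)[mid] - slow[mid])), 0.01)
  fast <- sin(2 * pi * 20 * t)
  expect_lt(max(abs(smooth_trajectory(fast, fs)[mid])), 0.1)
  expect_error(smooth_trajectory(c(1, Inf, 3), fs), "non-finite")
  expect_error(smooth_trajectory(1:100, 8), "twice the cutoff")
})

test_that("differentiation recovers closed-form derivatives", {
  fs <- 100
  t <- (0:499) / fs
  ramp <- differentiate(2.5 * t, fs)
  expect_equal(ramp$velocity, rep(2.5, 500), tolerance = 1e-9)
  expect_lt(max(abs(ramp$acceleration)), 1e-6)

  A <- 3; f <- 2
  d <- differentiate(A * sin(2 * pi * f * t), fs)
  mid <- 50:450
  expect_equal(max(abs(d$acceleration[mid])), A * (2 * pi * f)^2,
               tolerance = 0.01)
  expect_error(differentiate(1:3, fs), "5 samples")
})

test_that("cycle averaging reproduces a periodic signal exactly", {
  n_per <- 120L
  one <- sin(2 * pi * (0:(n_per - 1)) / n_per) + 2
  x <- rep(one, 5)
  hc <- seq(1L, by = n_per, length.out = 6L)
  avg <- normalize_cycle_average(x, hc)
  expect_length(avg, 100L)
  direct <- approx(seq_len(n_per), one,
                   xout = seq(1, n_per, length.out = 100))$y
  expect_equal(avg, direct, tolerance = 1e-9)
})

test_that("windowed peaks match a brute-force scan and flag edges", {
  acc <- cos(2 * pi * (1:100 - 55) / 100) * 100    # bump peaking at 55%
  w <- data.frame(label = "P5", joint = "knee", direction = "positive",
                  phase = "pre-swing", lo = 45, hi = 65)
  got <- find_peak_accelerations(list(knee = acc), w)
  expect_equal(got$timing, 55)
  expect_false(got$boundary)
  # uniform scaling moves magnitudes, not timings
  got2 <- find_peak_accelerations(list(knee = acc * 13), w)
  expect_equal(got2$timing, got$timing)
  expect_equal(got2$magnitude, got$magnitude * 13)

  # monotone trace peaks at the window edge and is flagged
  mono <- find_peak_accelerations(list(knee = seq_len(100)), w)
  expect_equal(mono$timing, 65)
  expect_true(mono$boundary)

  # random two-bump signals against an exhaustive scan
  set.seed(3)
  wins <- default_peak_windows()
  for (i in 1:10) {
    a <- rnorm(100)
    joints <- list(ankle = a, knee = rev(a), hip = a * -1)
    got <- find_peak_accelerations(joints, wins)
    for (r in seq_len(nrow(wins))) {
      idx <- which((1:100) >= wins$lo[r] & (1:100) <= wins$hi[r])
      sig <- joints[[wins$joint[r]]][idx]
      best <- if (wins$direction[r] == "positive") idx[which.max(sig)]
      else idx[which.min(sig)]
      expect_equal(got$timing[r], best)
    }
  }
  expect_error(
    find_peak_accelerations(list(knee = acc),
                            data.frame(label = "x", joint = "knee",
                                       direction = "positive",
                                       phase = "p", lo = 33.2, hi = 33.4)),
    "empty window")
})

test_that("quadratic speed trends are exact on parabolas and flat on constants", {
  s <- seq(2, 8, by = 0.5)
  y <- 1.5 - 2 * s + 0.7 * s^2
  fit <- fit_speed_trend(s, y)
  expect_equal(unname(fit$coefficients), c(1.5, -2, 0.7), tolerance = 1e-9)
  expect_equal(fit$fitted, y, tolerance = 1e-9)

  flat <- fit_speed_trend(s, rep(4, length(s)))
  expect_equal(unname(flat$coefficients), c(4, 0, 0), tolerance = 1e-9)

  expect_error(fit_speed_trend(c(2, 2, 4, 4), c(1, 2, 3, 4)),
               "3 distinct speeds")

  # noisy parabola: recovered coefficients stay near the truth on average
  set.seed(4)
  est <- replicate(100, {
    yn <- y + rnorm(length(s), 0, 0.3)
    fit_speed_trend(s, yn)$coefficients["quadratic"]
  })
  expect_equal(mean(est), 0.7, tolerance = 0.05)
})

test_that("kinematic processing finds in-window peaks that grow with speed", {
  peaks_at <- function(speed) {
    cfg <- trial_config(speed = speed, n_cycles = 40L, seed = 6L)
    process_kinematics(synthesize_kinematics(cfg))$peaks
  }
  p4 <- peaks_at(4)
  expect_equal(nrow(p4), 11L)
  wins <- default_peak_windows()
  expect_true(all(p4$timing >= wins$lo & p4$timing <= wins$hi))
  p8 <- peaks_at(8)
  expect_gt(mean(abs(p8$magnitude)) / mean(abs(p4$magnitude)), 1)
})
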