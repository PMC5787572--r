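# Center of activity: the circular first moment of an activation profile
# on the gait-cycle circle, plus the across-speed comparisons.

#' Center of activity of an activation profile
#'
#' The gait cycle (bins `t = 1..n`) is mapped onto the circle with
#' `theta_t = t * 360 / n` degrees (3.6° per percent bin for the standard
#' 100-bin cycle), and the CoA is the direction of the activation-weighted
#' mean vector: `A = sum(cos(theta) * act)`, `B = sum(sin(theta) * act)`,
#' `CoA = atan2(B, A)` mapped to `[0, 360)`.  The two-argument arctangent
#' is essential — a plain `atan(B/A)` would misplace centers in quadrants
#' II-IV.
#'
#' @param act Non-negative activation values over one normalized cycle
#'   (length 100 for the standard cycle; any length is accepted).
#' @return List of class `coa_estimate`: `A`, `B`, `coa_deg` in
#'   `[0, 360)`, `coa_pct` in `[0, 100)`, `resultant_length`
#'   (`sqrt(A^2 + B^2) / sum(act)`, 1 = concentrated, 0 = balanced).
#' @export
center_of_activity <- function(act) {
  act <- as.numeric(act)
  if (anyNA(act) || any(!is.finite(act))) {
    stop("activation contains non-finite values", call. = FALSE)
  }
  stop_if_negative(act, "act")
  total <- sum(act)
  if (total <= 0) {
    stop("CoA undefined: all-zero activation", call. = FALSE)
  }
  n <- length(act)
  theta <- seq_len(n) * 2 * pi / n
  A <- sum(cos(theta) * act)
  B <- sum(sin(theta) * act)
  r <- sqrt(A^2 + B^2) / total
  if (r < 1e-9) {
    stop("CoA undefined: zero resultant (balanced activation)",
         call. = FALSE)
  }
  coa_deg <- canonical_deg(atan2(B, A) * 180 / pi)
  structure(
    list(A = A, B = B, coa_deg = coa_deg, coa_pct = coa_deg / 3.6,
         resultant_length = r),
    class = "coa_estimate")
}

#' @export
print.coa_estimate <- function(x, ...) {
  cat(sprintf("CoA: %.1f deg (%.1f%% of cycle), resultant length %.3f\n",
              x$coa_deg, x$coa_pct, x$resultant_length))
  invisible(x)
}

#' Circular mean of a set of angles
#'
#' Direction of the mean unit vector; the wraparound-safe average used for
#' the across-subject mean CoA.
#'
#' @param angles_deg Angles in degrees.
#' @return List with `mean_deg` in `[0, 360)` and `resultant_length`.
#' @export
circular_mean <- function(angles_deg) {
  if (length(angles_deg) == 0L) stop("empty angle set", call. = FALSE)
  rad <- angles_deg * pi / 180
  A <- mean(cos(rad)); B <- mean(sin(rad))
  r <- sqrt(A^2 + B^2)
  if (r < 1e-9) {
    stop("circular mean undefined: zero resultant", call. = FALSE)
  }
  list(mean_deg = canonical_deg(atan2(B, A) * 180 / pi),
       resultant_length = r)
}

# Map an angle to [0, 360), collapsing values within numerical noise of a
# full turn onto 0.
canonical_deg <- function(deg) {
  deg <- deg %% 360
  if (deg >= 360 - 1e-9) 0 else deg
}

#' Unwrap circular values about a center for linear statistics
#'
#' Adds or subtracts full turns so every angle lies within half a turn of
#' `center` (default: the set's circular mean).  Values straddling the
#' 0/360 wrap point become contiguous, so ordinary ANOVA and t-tests see
#' the true (small) differences rather than artifactual ~360 jumps.
#'
#' @param angles_deg Angles in degrees.
#' @param center Center angle in degrees; `NULL` uses the circular mean.
#' @param period Circle period (360 for degrees, 100 for % gait cycle).
#' @return Numeric vector on the linear scale.
#' @export
unwrap_angles <- function(angles_deg, center = NULL, period = 360) {
  if (is.null(center)) {
    center <- circular_mean(angles_deg * 360 / period)$mean_deg *
      period / 360
  }
  ((angles_deg - center + period / 2) %% period) - period / 2 + center
}

#' Compare CoA across walking speeds: one-way ANOVA + Tukey-Kramer
#'
#' CoAs (one per subject per speed) are unwrapped about their grand
#' circular mean, then compared across speed conditions with a one-way
#' ANOVA and all-pairs Tukey-Kramer post hoc tests at `alpha`.
#'
#' @param coa_deg CoA values in degrees.
#' @param speed Speed condition of each value (coerced to factor).
#' @param alpha Significance level (default 0.05).
#' @param unwrap Unwrap about the grand circular mean first (default
#'   `TRUE`; disable for strict linear treatment of the raw angles).
#' @return List with `anova` (the `aov` summary table), `p_value`,
#'   `tukey` (data frame of pairwise comparisons with `diff`, `lwr`,
#'   `upr`, `p_adj`, `significant`), `grand_mean_deg`.
#' @export
compare_coa_across_speeds <- function(coa_deg, speed, alpha = 0.05,
                                      unwrap = TRUE) {
  speed <- factor(speed)
  if (nlevels(speed) < 2L) {
    stop("need at least two speed conditions", call. = FALSE)
  }
  if (any(table(speed) < 2L)) {
    stop("every speed condition needs at least two CoA values",
         call. = FALSE)
  }
  gm <- circular_mean(coa_deg)$mean_deg
  y <- if (unwrap) unwrap_angles(coa_deg, center = gm) else coa_deg
  fit <- aov(y ~ speed, data = data.frame(y = y, speed = speed))
  tab <- summary(fit)[[1]]
  p <- tab[["Pr(>F)"]][1]
  tk <- TukeyHSD(fit, conf.level = 1 - alpha)$speed
  tukey <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"],
                      significant = tk[, "p adj"] < alpha,
                      row.names = NULL)
  list(anova = tab, p_value = p, tukey = tukey, grand_mean_deg = gm)
}

#' Compare two sets of CoAs with an unpaired Student's t-test
#'
#' Both samples are unwrapped about their pooled circular mean first, so
#' clusters straddling the wrap point compare by their true separation.
#'
#' @param a,b CoA samples in degrees (each of length >= 2).
#' @param unwrap Unwrap about the pooled circular mean (default `TRUE`).
#' @return List with `t`, `df`, `p_value`, `mean_diff_deg`.
#' @export
compare_two_coa <- function(a, b, unwrap = TRUE) {
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs at least two values", call. = FALSE)
  }
  if (unwrap) {
    gm <- circular_mean(c(a, b))$mean_deg
    a <- unwrap_angles(a, center = gm)
    b <- unwrap_angles(b, center = gm)
  }
  if (sd(c(a, b)) <= 1e-12) {
    if (abs(mean(a) - mean(b)) <= 1e-12) {
      return(list(t = 0, df = length(a) + length(b) - 2L, p_value = 1,
                  mean_diff_deg = 0))
    }
    stop("degenerate variance: groups are constant but different",
         call. = FALSE)
  }
  if (sd(a) <= 1e-12 && sd(b) <= 1e-12) {
    stop("degenerate variance in both groups", call. = FALSE)
  }
  ht <- t.test(a, b, var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, mean_diff_deg = mean(a) - mean(b))
}
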