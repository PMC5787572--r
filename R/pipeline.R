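# End-to-end orchestration: simulate (or load) recordings, preprocess,
# extract and select synergies, run the shuffle control, group synergies
# across subjects, compute CoA statistics across speeds, and process
# kinematics.  All randomness flows from one root seed through per-stage
# derived seeds.

#' Pipeline configuration
#'
#' @param speeds Walking speeds, km/h (default the 13 controlled treadmill
#'   speeds 2.0-8.0 in 0.5 steps plus the 4.3 km/h mean preferred speed).
#' @param subjects Number of synthetic subjects (default 3).
#' @param n_synergies `NULL` to select the number per subject/speed by
#'   cross-validated VAF, or a fixed integer.
#' @param max_rank Highest rank tried during selection.
#' @param n_cycles Simulated cycles per trial (default 45).
#' @param envelope_noise_sd Generator noise level (default 0.05).
#' @param subject_weighting_sd Between-subject perturbation of the shared
#'   ground-truth weightings (default 0.05).
#' @param subject_center_sd Between-subject jitter of activation centers,
#'   % gait cycle (default 1).
#' @param n_restarts NMF restarts (default 20).
#' @param cv_repetitions Cross-validation repetitions (default 10).
#' @param threshold Grouping similarity cutoff (default 0.71).
#' @param global_threshold,muscle_threshold VAF selection thresholds.
#' @param run_shuffle_check Run the surrogate-data control (default
#'   `TRUE`).
#' @param ground_truth A [gait_synergies()] object used when simulating;
#'   `NULL` means [default_ground_truth()].
#' @param seed Root seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(speeds = c(seq(2, 8, by = 0.5), 4.3),
                            subjects = 3L, n_synergies = NULL,
                            max_rank = 8L, n_cycles = 45L,
                            envelope_noise_sd = 0.05,
                            subject_weighting_sd = 0.05,
                            subject_center_sd = 1,
                            n_restarts = 20L, cv_repetitions = 10L,
                            threshold = 0.71, global_threshold = 90,
                            muscle_threshold = 75,
                            run_shuffle_check = TRUE,
                            ground_truth = NULL, seed = 1L) {
  if (length(speeds) == 0L) stop("speeds must be non-empty", call. = FALSE)
  if (threshold <= 0 || threshold >= 1) {
    stop("threshold must lie in (0, 1)", call. = FALSE)
  }
  structure(as.list(environment()), class = "pipeline_config")
}

# Perturb the shared ground truth into one subject's own synergy
# structure: weighting noise plus activation-timing jitter.
subject_ground_truth <- function(gt, sd, seed, center_sd = 1) {
  if (sd <= 0 && center_sd <= 0) return(gt)
  set.seed(seed)
  w <- pmax(gt$weightings + matrix(rnorm(length(gt$weightings), 0, sd),
                                   nrow(gt$weightings)), 1e-6)
  w <- sweep(w, 2, col_norms(w), "/")
  centers <- (gt$profile_centers +
                rnorm(length(gt$profile_centers), 0, center_sd)) %% 100
  gait_synergies(w, centers, gt$profile_widths,
                 gt$profile_amplitudes, gt$coa_slopes, gt$reference_speed)
}

#' Run the full synergy/CoA analysis pipeline
#'
#' Stages per subject and speed: simulate (or accept) a recording,
#' preprocess to the normalized cycle matrix, select the number of
#' synergies (or use the configured one), extract the final decomposition,
#' then across subjects: group synergies against a reference subject,
#' compute each synergy group's center of activity per subject and speed,
#' compare CoA across speeds (ANOVA + Tukey-Kramer), fit CoA-vs-speed
#' slopes, run the shuffle control on the reference subject, and process
#' synthetic kinematics into peak-acceleration speed trends.  Re-running
#' with an identical config reproduces identical results.
#'
#' @param config A [pipeline_config()].
#' @param recordings Optional list of lists of [emg_recording()]s indexed
#'   as `recordings[[subject]][[as.character(speed)]]`; `NULL` simulates
#'   from the default ground truth.
#' @param output_dir Optional directory; when given, result tables are
#'   written as CSV/JSON.
#' @return An object of class `pipeline_result` with elements
#'   `selected_n` (subject x speed matrix), `consensus_n`,
#'   `decompositions`, `grouping`, `coa_table` (data frame), `coa_anova`
#'   (per group), `coa_slopes` (per group linear trend), `shuffle`,
#'   `kinematic_peaks`, `peak_trends`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), recordings = NULL,
                         output_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  gt <- if (is.null(config$ground_truth)) default_ground_truth()
  else config$ground_truth
  speeds <- config$speeds
  n_sub <- config$subjects
  speed_keys <- as.character(speeds)

  selected <- matrix(NA_integer_, n_sub, length(speeds),
                     dimnames = list(paste0("S", seq_len(n_sub)),
                                     speed_keys))
  decomps <- list()
  sets <- list()
  matrices <- list()

  for (s in seq_len(n_sub)) {
    gt_s <- subject_ground_truth(gt, config$subject_weighting_sd,
                                 derive_seed(config$seed,
                                             sprintf("subject%02d", s)),
                                 config$subject_center_sd)
    for (v in seq_along(speeds)) {
      key <- sprintf("S%d@%s", s, speed_keys[v])
      seed_sv <- derive_seed(config$seed, key)
      rec <- if (is.null(recordings)) {
        cfg <- trial_config(speed = speeds[v], n_cycles = config$n_cycles,
                            envelope_noise_sd = config$envelope_noise_sd,
                            seed = seed_sv)
        synthesize_emg(gt_s, cfg)
      } else {
        recordings[[s]][[speed_keys[v]]]
      }
      cm <- preprocess_recording(rec)
      matrices[[key]] <- cm
      n_syn <- config$n_synergies
      if (is.null(n_syn)) {
        sel <- select_rank(cm,
                           crossval_scheme(n_repetitions =
                                             config$cv_repetitions,
                                           seed = derive_seed(seed_sv,
                                                              "cv")),
                           config$global_threshold,
                           config$muscle_threshold,
                           max_rank = config$max_rank,
                           n_restarts = config$n_restarts)
        n_syn <- sel$selected_n
        if (is.na(n_syn)) n_syn <- config$max_rank
      }
      selected[s, v] <- n_syn
      dec <- fit_nmf(cm, n_syn, n_restarts = config$n_restarts,
                     seed = derive_seed(seed_sv, "final"))
      decomps[[key]] <- dec
      sets[[key]] <- list(W = dec$W, C = activation_template(dec$C))
    }
  }

  consensus <- consensus_num(as.vector(selected))

  # group against the reference subject at the median speed
  ref_key <- sprintf("S1@%s",
                     speed_keys[which.min(abs(speeds - median(speeds)))])
  grouping <- group_synergies(sets,
                              reference_index = match(ref_key, names(sets)),
                              threshold = config$threshold)

  # CoA of every matched synergy
  rows <- list()
  for (key in names(sets)) {
    a <- grouping$assignments[[key]]
    parts <- strsplit(key, "@", fixed = TRUE)[[1]]
    for (r in seq_len(nrow(a))) {
      if (is.na(a$group[r])) next
      est <- tryCatch(
        center_of_activity(sets[[key]]$C[a$candidate[r], ]),
        error = function(e) NULL)
      if (is.null(est)) next
      rows[[length(rows) + 1L]] <- data.frame(
        subject = parts[1], speed = as.numeric(parts[2]),
        group = a$group[r], coa_deg = est$coa_deg,
        coa_pct = est$coa_pct, similarity = a$similarity[r])
    }
  }
  coa_table <- do.call(rbind, rows)

  coa_anova <- list(); coa_slopes <- list()
  for (g in sort(unique(coa_table$group))) {
    sub <- coa_table[coa_table$group == g, ]
    if (length(unique(sub$speed)) >= 2L && all(table(sub$speed) >= 2L)) {
      coa_anova[[as.character(g)]] <-
        compare_coa_across_speeds(sub$coa_deg, sub$speed)
    }
    if (length(unique(sub$speed)) >= 2L) {
      y <- unwrap_angles(sub$coa_pct, period = 100)
      fit <- lm(y ~ speed, data = data.frame(y = y, speed = sub$speed))
      ci <- tryCatch(stats::confint(fit)["speed", ],
                     error = function(e) c(NA_real_, NA_real_))
      coa_slopes[[as.character(g)]] <- list(
        slope_pct_per_kmh = unname(coef(fit)["speed"]),
        ci95 = unname(ci))
    }
  }

  shuffle <- NULL
  if (config$run_shuffle_check) {
    shuffle <- compare_shuffled_vaf(
      matrices[[ref_key]], ranks = seq_len(min(consensus, config$max_rank)),
      n_restarts = config$n_restarts,
      seed = derive_seed(config$seed, "shuffle"))
  }

  # kinematics: one synthetic trial per speed, peaks and quadratic trends
  peak_rows <- list()
  for (v in seq_along(speeds)) {
    cfg <- trial_config(speed = speeds[v], n_cycles = config$n_cycles,
                        seed = derive_seed(config$seed,
                                           paste0("kin", speed_keys[v])))
    kp <- process_kinematics(synthesize_kinematics(cfg))$peaks
    kp$speed <- speeds[v]
    peak_rows[[v]] <- kp
  }
  kinematic_peaks <- do.call(rbind, peak_rows)
  peak_trends <- list()
  if (length(unique(speeds)) >= 3L) {
    for (lab in unique(kinematic_peaks$label)) {
      sub <- kinematic_peaks[kinematic_peaks$label == lab, ]
      peak_trends[[lab]] <- fit_speed_trend(sub$speed, sub$magnitude)
    }
  }

  result <- structure(
    list(selected_n = selected, consensus_n = consensus,
         decompositions = decomps, grouping = grouping,
         coa_table = coa_table, coa_anova = coa_anova,
         coa_slopes = coa_slopes, shuffle = shuffle,
         kinematic_peaks = kinematic_peaks, peak_trends = peak_trends,
         config = config),
    class = "pipeline_result")

  if (!is.null(output_dir)) write_pipeline_result(result, output_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("Pipeline result: %d subjects x %d speeds, consensus N = %d\n",
              nrow(x$selected_n), ncol(x$selected_n), x$consensus_n))
  if (!is.null(x$coa_table)) {
    cat(sprintf("  CoA table: %d rows over %d synergy groups\n",
                nrow(x$coa_table), length(unique(x$coa_table$group))))
  }
  invisible(x)
}

#' Write pipeline result tables to a directory
#'
#' Emits `selected_n.csv`, `coa_table.csv`, `coa_slopes.json`,
#' `shuffle_vaf.csv`, `kinematic_peaks.csv`, `peak_trends.json` and, when
#' ggplot2 is available, a polar CoA summary figure per synergy group.
#'
#' @param result A `pipeline_result`.
#' @param output_dir Directory (created if missing).
#' @return Invisibly, `output_dir`.
#' @export
write_pipeline_result <- function(result, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(result$selected_n),
                   file.path(output_dir, "selected_n.csv"))
  utils::write.csv(result$coa_table,
                   file.path(output_dir, "coa_table.csv"),
                   row.names = FALSE)
  jsonlite::write_json(result$coa_slopes,
                       file.path(output_dir, "coa_slopes.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(result$shuffle)) {
    utils::write.csv(result$shuffle,
                     file.path(output_dir, "shuffle_vaf.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(result$kinematic_peaks,
                   file.path(output_dir, "kinematic_peaks.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    lapply(result$peak_trends, function(t)
      list(coefficients = as.list(t$coefficients))),
    file.path(output_dir, "peak_trends.json"),
    auto_unbox = TRUE, digits = NA)
  if (requireNamespace("ggplot2", quietly = TRUE) &&
      !is.null(result$coa_table)) {
    p <- plot_coa_polar(result$coa_table)
    ggplot2::ggsave(file.path(output_dir, "coa_polar.pdf"), p,
                    width = 7, height = 6)
  }
  invisible(output_dir)
}

#' Polar summary of CoA across speeds
#'
#' One point per (subject, speed, synergy group) on the gait-cycle circle,
#' colored by speed and faceted by group; the radial coordinate is walking
#' speed so the speed-dependent drift of each group is visible at a
#' glance.
#'
#' @param coa_table Data frame with `group`, `speed`, `coa_pct` (as in
#'   `pipeline_result$coa_table`).
#' @return A ggplot object.
#' @export
plot_coa_polar <- function(coa_table) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  ggplot2::ggplot(coa_table,
                  ggplot2::aes(x = coa_pct, y = speed, color = speed)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::coord_polar(theta = "x") +
    ggplot2::scale_x_continuous(limits = c(0, 100),
                                breaks = seq(0, 75, by = 25),
                                name = "% gait cycle") +
    ggplot2::facet_wrap(~group, labeller = ggplot2::label_both) +
    ggplot2::labs(y = "speed (km/h)", color = "km/h") +
    ggplot2::theme_minimal()
}
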