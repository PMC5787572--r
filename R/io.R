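# Plain-text interchange: EMG and kinematics as CSV with a JSON sidecar.

#' Write an EMG recording as CSV plus JSON sidecar
#'
#' The CSV has columns `time_s`, one column per muscle, and `footswitch`
#' (1 at heel-contact samples, else 0).  The sidecar records `fs`, `speed`,
#' `muscle_labels` and, when present, the generator's seed and ground
#' truth.
#'
#' @param rec An [emg_recording()].
#' @param csv_path,json_path Output paths.
#' @return Invisibly, the CSV path.
#' @export
write_emg_csv <- function(rec, csv_path, json_path = NULL) {
  n <- ncol(rec$signals)
  foot <- integer(n)
  foot[rec$heel_contacts] <- 1L
  df <- data.frame(time_s = (seq_len(n) - 1) / rec$fs,
                   t(rec$signals), footswitch = foot, check.names = FALSE)
  names(df) <- c("time_s", rec$muscle_labels, "footswitch")
  utils::write.csv(df, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    gt <- attr(rec, "ground_truth")
    side <- list(fs = rec$fs, speed = rec$speed,
                 muscle_labels = rec$muscle_labels)
    if (!is.null(gt)) {
      side$ground_truth <- list(
        weightings = unname(gt$weightings),
        profile_centers = gt$profile_centers,
        profile_widths = gt$profile_widths,
        profile_amplitudes = gt$profile_amplitudes,
        coa_slopes = gt$coa_slopes,
        reference_speed = gt$reference_speed)
    }
    jsonlite::write_json(side, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(csv_path)
}

#' Read an EMG recording written by [write_emg_csv()]
#'
#' @param csv_path CSV path.
#' @param json_path Optional sidecar; when absent, `fs` is inferred from
#'   the time column and `speed` is `NA`.
#' @param muscle_labels Channels expected in the CSV (default the standard
#'   12-muscle montage); a missing column is an error naming the muscle.
#' @return An [emg_recording()].
#' @export
read_emg_csv <- function(csv_path, json_path = NULL,
                         muscle_labels = NULL) {
  df <- utils::read.csv(csv_path, check.names = FALSE)
  side <- if (!is.null(json_path)) jsonlite::read_json(json_path,
                                                       simplifyVector = TRUE)
  if (is.null(muscle_labels)) {
    muscle_labels <- if (!is.null(side)) side$muscle_labels
    else setdiff(names(df), c("time_s", "footswitch"))
  }
  missing <- setdiff(muscle_labels, names(df))
  if (length(missing)) {
    stop(sprintf("missing muscle channel(s) in CSV: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  fs <- if (!is.null(side)) side$fs else 1 / median(diff(df$time_s))
  speed <- if (!is.null(side)) side$speed else NA_real_
  emg_recording(t(as.matrix(df[, muscle_labels])), fs, muscle_labels,
                which(df$footswitch == 1L), speed)
}

#' Write joint-angle trajectories as CSV
#'
#' Columns: `time_s`, `ankle_deg`, `knee_deg`, `hip_deg`, `footswitch`.
#'
#' @param trial A [synthesize_kinematics()] result.
#' @param csv_path Output path.
#' @return Invisibly, the path.
#' @export
write_kinematics_csv <- function(trial, csv_path) {
  n <- length(trial$angle[[1]])
  foot <- integer(n)
  foot[trial$heel_contacts[trial$heel_contacts <= n]] <- 1L
  df <- data.frame(time_s = (seq_len(n) - 1) / trial$fs,
                   ankle_deg = trial$angle$ankle,
                   knee_deg = trial$angle$knee,
                   hip_deg = trial$angle$hip,
                   footswitch = foot)
  utils::write.csv(df, csv_path, row.names = FALSE)
  invisible(csv_path)
}

#' Serialize a VAF report to JSON and a per-muscle table to CSV
#'
#' @param report A [vaf_report()].
#' @param json_path JSON output path (`NULL` to skip).
#' @param csv_path CSV output path for the per-rank, per-muscle held-out
#'   VAF means (`NULL` to skip).
#' @return Invisibly, `report`.
#' @export
write_vaf_report <- function(report, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path)) {
    payload <- lapply(report, function(s) {
      list(rank = s$rank, global = s$global,
           muscle = as.data.frame(t(s$muscle)),
           train_global = s$train_global,
           ci95_global = as.list(ci_bounds(s$global)))
    })
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE,
                         digits = NA, dataframe = "columns")
  }
  if (!is.null(csv_path)) {
    rows <- do.call(rbind, lapply(report, function(s) {
      data.frame(rank = s$rank, muscle = rownames(s$muscle),
                 mean_vaf = rowMeans(s$muscle),
                 ci95_lower = apply(s$muscle, 1, function(v)
                   ci_bounds(v)["lower"]),
                 row.names = NULL)
    }))
    utils::write.csv(rows, csv_path, row.names = FALSE)
  }
  invisible(report)
}
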