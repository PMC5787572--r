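# Cross-validated variance-accounted-for computation and the rule for
# choosing the number of synergies.

#' Variance accounted for by a reconstruction
#'
#' `VAF = 100 * (1 - SSE / SST)` with uncentred sums of squares, computed
#' over the whole matrix (`scope = "global"`) or per muscle row
#' (`scope = "muscle"`).
#'
#' @param emg_o Original matrix (or vector).
#' @param emg_r Reconstructed matrix of the same shape.
#' @param scope `"global"` or `"muscle"`.
#' @return Percentage (global) or named numeric vector of percentages
#'   (per muscle).
#' @export
vaf <- function(emg_o, emg_r, scope = c("global", "muscle")) {
  scope <- match.arg(scope)
  if (is.vector(emg_o)) emg_o <- matrix(emg_o, nrow = 1L)
  if (is.vector(emg_r)) emg_r <- matrix(emg_r, nrow = 1L)
  if (!all(dim(emg_o) == dim(emg_r))) {
    stop("emg_o and emg_r must have the same shape", call. = FALSE)
  }
  if (scope == "global") {
    sst <- sum(emg_o^2)
    if (sst <= 0) stop("zero-energy original matrix", call. = FALSE)
    return(100 * (1 - sum((emg_o - emg_r)^2) / sst))
  }
  sst <- rowSums(emg_o^2)
  if (any(sst <= 0)) {
    stop("zero-energy muscle row in the original matrix", call. = FALSE)
  }
  out <- 100 * (1 - rowSums((emg_o - emg_r)^2) / sst)
  names(out) <- rownames(emg_o)
  out
}

#' Cross-validation scheme for the synergy-number selection
#'
#' @param train_cycles Gait cycles used for extraction (default 18, i.e.
#'   60% of the 30 analyzed cycles).
#' @param test_cycles Held-out cycles (default 12, i.e. 40%).
#' @param n_repetitions Random train/test splits (default 10).
#' @param seed Integer seed controlling the partitions and NMF restarts.
#' @return An object of class `crossval_scheme`.
#' @export
crossval_scheme <- function(train_cycles = 18L, test_cycles = 12L,
                            n_repetitions = 10L, seed = 1L) {
  structure(
    list(train_cycles = as.integer(train_cycles),
         test_cycles = as.integer(test_cycles),
         train_fraction = train_cycles / (train_cycles + test_cycles),
         n_repetitions = as.integer(n_repetitions),
         seed = as.integer(seed)),
    class = "crossval_scheme")
}

# Column indices of a set of cycles in a concatenated cycle matrix.
cycle_columns <- function(cycles, n_bins) {
  as.vector(vapply(sort(cycles),
                   function(k) (k - 1L) * n_bins + seq_len(n_bins),
                   integer(n_bins)))
}

#' Cross-validated VAF at one candidate rank
#'
#' Per repetition: sample `train_cycles` whole gait cycles without
#' replacement, extract synergies from them ([fit_nmf()]), refit only the
#' activations on the remaining test cycles with the training weightings
#' fixed ([fit_activations_fixed_w()]), and score global and per-muscle
#' VAF on the held-out reconstruction.
#'
#' @param cm A [cycle_matrix()] whose cycle count equals
#'   `train_cycles + test_cycles`.
#' @param N Candidate number of synergies.
#' @param scheme A [crossval_scheme()].
#' @param n_restarts NMF restarts per training fit (default 20).
#' @param max_iter,tol Passed to [fit_nmf()].
#' @return List with `rank`, `global` (one held-out global VAF per
#'   repetition), `muscle` (muscles x repetitions matrix), and the
#'   training-side `train_global` per repetition.
#' @export
crossval_vaf <- function(cm, N, scheme = crossval_scheme(),
                         n_restarts = 20L, max_iter = 1000L, tol = 1e-6) {
  stopifnot(inherits(cm, "cycle_matrix"))
  n_cyc <- cm$n_cycles
  if (n_cyc != scheme$train_cycles + scheme$test_cycles) {
    stop(sprintf("cycle matrix has %d cycles; scheme needs %d",
                 n_cyc, scheme$train_cycles + scheme$test_cycles),
         call. = FALSE)
  }
  nrep <- scheme$n_repetitions
  glob <- train_glob <- numeric(nrep)
  musc <- matrix(NA_real_, nrow(cm$values), nrep,
                 dimnames = list(rownames(cm$values), NULL))
  for (i in seq_len(nrep)) {
    rep_seed <- derive_seed(scheme$seed, sprintf("rep%03d", i))
    set.seed(rep_seed)
    train <- sample(n_cyc, scheme$train_cycles)
    test <- setdiff(seq_len(n_cyc), train)
    M_train <- cm$values[, cycle_columns(train, cm$n_bins), drop = FALSE]
    M_test <- cm$values[, cycle_columns(test, cm$n_bins), drop = FALSE]
    dec <- fit_nmf(M_train, N, n_restarts = n_restarts,
                   seed = derive_seed(rep_seed, sprintf("rank%02d", N)),
                   max_iter = max_iter, tol = tol)
    C_test <- fit_activations_fixed_w(M_test, dec$W)
    recon <- dec$W %*% C_test
    glob[i] <- vaf(M_test, recon, "global")
    musc[, i] <- vaf(M_test, recon, "muscle")
    train_glob[i] <- 100 * (1 - dec$residual_sse / sum(M_train^2))
  }
  list(rank = as.integer(N), global = glob, muscle = musc,
       train_global = train_glob)
}

#' Assemble a VAF report over a range of ranks
#'
#' @param cm A [cycle_matrix()].
#' @param ranks Candidate ranks (default `1:nrow`).
#' @inheritParams crossval_vaf
#' @return An object of class `vaf_report`: list of per-rank results from
#'   [crossval_vaf()], indexed by rank.
#' @export
vaf_report <- function(cm, ranks = seq_len(nrow(cm$values)),
                       scheme = crossval_scheme(), n_restarts = 20L,
                       max_iter = 1000L, tol = 1e-6) {
  out <- lapply(ranks, function(N) {
    crossval_vaf(cm, N, scheme, n_restarts, max_iter, tol)
  })
  names(out) <- as.character(ranks)
  structure(out, class = "vaf_report")
}

#' @export
print.vaf_report <- function(x, ...) {
  cat("Cross-validated VAF report\n")
  for (slice in x) {
    lb <- ci_bounds(slice$global)["lower"]
    cat(sprintf("  N = %2d: held-out global VAF %.2f%% (95%% CI lower %.2f%%)\n",
                slice$rank, mean(slice$global), lb))
  }
  invisible(x)
}

# Does one rank slice pass the two CI-lower-bound thresholds?
rank_passes <- function(slice, global_threshold, muscle_threshold,
                        level = 0.95) {
  lb_g <- ci_bounds(slice$global, level)["lower"]
  lb_m <- apply(slice$muscle, 1, function(v) ci_bounds(v, level)["lower"])
  lb_g > global_threshold && all(lb_m > muscle_threshold)
}

#' Select the number of synergies from a VAF report
#'
#' The number of synergies underlying a dataset is the smallest rank at
#' which the lower bound of the 95% confidence interval (t-based, across
#' cross-validation repetitions) strictly exceeds `global_threshold` for
#' global VAF and `muscle_threshold` for every muscle's VAF.
#'
#' @param report A [vaf_report()] covering consecutive ranks from 1.
#' @param global_threshold Global VAF threshold, % (default 90).
#' @param muscle_threshold Per-muscle VAF threshold, % (default 75).
#' @return Smallest qualifying rank, or `NA_integer_` if none qualifies.
#' @export
select_num_synergies <- function(report, global_threshold = 90,
                                 muscle_threshold = 75) {
  ranks <- vapply(report, `[[`, integer(1), "rank")
  if (length(ranks) == 0L || ranks[1] != 1L ||
      any(diff(ranks) != 1L)) {
    stop("report must cover consecutive ranks starting at 1",
         call. = FALSE)
  }
  for (slice in report) {
    if (rank_passes(slice, global_threshold, muscle_threshold)) {
      return(slice$rank)
    }
  }
  NA_integer_
}

#' Incremental rank scan with early stopping
#'
#' Evaluates [crossval_vaf()] at ranks 1, 2, ... and stops at the first
#' rank whose CI lower bounds pass both thresholds — the same answer as
#' scoring a full report with [select_num_synergies()], at a fraction of
#' the cost.
#'
#' @inheritParams vaf_report
#' @inheritParams select_num_synergies
#' @param max_rank Highest rank to try (default `nrow`).
#' @return List with `selected_n` (or `NA`) and `report` (the evaluated
#'   slices, a [vaf_report()]).
#' @export
select_rank <- function(cm, scheme = crossval_scheme(),
                        global_threshold = 90, muscle_threshold = 75,
                        max_rank = nrow(cm$values), n_restarts = 20L,
                        max_iter = 1000L, tol = 1e-6) {
  slices <- list()
  selected <- NA_integer_
  for (N in seq_len(max_rank)) {
    slice <- crossval_vaf(cm, N, scheme, n_restarts, max_iter, tol)
    slices[[as.character(N)]] <- slice
    if (rank_passes(slice, global_threshold, muscle_threshold)) {
      selected <- N
      break
    }
  }
  list(selected_n = selected,
       report = structure(slices, class = "vaf_report"))
}

#' Consensus number of synergies across subjects
#'
#' Median across subjects, rounded half-up to an integer.
#'
#' @param per_subject_n Integer vector of per-subject selections.
#' @return Integer consensus count.
#' @export
consensus_num <- function(per_subject_n) {
  if (length(per_subject_n) == 0L) {
    stop("per_subject_n must be non-empty", call. = FALSE)
  }
  as.integer(floor(median(per_subject_n) + 0.5))
}
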