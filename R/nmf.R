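# Non-negative matrix factorization by Lee-Seung multiplicative updates,
# with multi-restart selection and a fixed-weightings mode for
# cross-validated activation refits.

#' Normalize a factorization so weighting columns are unit vectors
#'
#' Scales each weighting column to unit Euclidean norm and compensates the
#' matching activation row, leaving the product `W %*% C` unchanged.
#'
#' @param W Non-negative muscles x N matrix with no all-zero column.
#' @param C Non-negative N x time matrix.
#' @return List with `W` (unit-norm columns) and `C`.
#' @export
normalize_decomposition <- function(W, C) {
  norms <- col_norms(W)
  if (any(norms <= 1e-12)) {
    stop("cannot normalize: weighting column with zero norm", call. = FALSE)
  }
  list(W = sweep(W, 2, norms, "/"), C = C * norms)
}

# CoA (in bins) of the cycle-averaged activation of each row of C; used
# only to order synergies for stable display.  Undefined CoAs sort last.
activation_order <- function(C, n_bins = 100L) {
  scores <- apply(C, 1, function(row) {
    prof <- if (length(row) %% n_bins == 0L) {
      rowMeans(matrix(row, n_bins))
    } else row
    out <- tryCatch(center_of_activity(prof)$coa_pct,
                    error = function(e) Inf)
    out
  })
  order(scores)
}

#' Fit a muscle synergy decomposition by multiplicative-update NMF
#'
#' Minimizes the squared Frobenius reconstruction error of
#' `M ~ W %*% C` under non-negativity, from `n_restarts` independent
#' uniform-random initializations scaled to the matrix mean; the restart
#' with the smallest residual wins (ties: lowest restart index).  The
#' winning factorization is normalized to unit-norm weighting columns and
#' its synergies ordered by ascending center of activity.
#'
#' @param M Non-negative matrix, muscles x time.
#' @param N Number of synergies, `1 <= N <= nrow(M)`.
#' @param n_restarts Independent random initializations (default 20).
#' @param seed Integer seed; the fit is a pure function of `(M, N, seed)`.
#' @param max_iter Update-iteration cap per restart (default 1000).
#' @param tol Relative residual decrease below which updates stop
#'   (default 1e-6).
#' @return An object of class `synergy_decomposition`: `W`, `C`,
#'   `residual_sse`, `N`, `converged`, `iterations`, `seed`,
#'   `restart_sse` (all restarts' residuals).
#' @export
fit_nmf <- function(M, N, n_restarts = 20L, seed = 1L, max_iter = 1000L,
                    tol = 1e-6) {
  if (inherits(M, "cycle_matrix")) M <- M$values
  stop_if_not_matrix(M)
  stop_if_negative(M)
  N <- as.integer(N)
  if (N < 1L || N > nrow(M)) {
    stop(sprintf("N must be in 1..%d", nrow(M)), call. = FALSE)
  }
  set.seed(as.integer(seed))
  m <- nrow(M); tt <- ncol(M)
  scale <- sqrt(max(mean(M), 1e-12) / N)
  best <- NULL
  restart_sse <- numeric(n_restarts)
  for (r in seq_len(n_restarts)) {
    W0 <- matrix(pmax(runif(m * N), 1e-6) * scale, m, N)
    C0 <- matrix(pmax(runif(N * tt), 1e-6) * scale, N, tt)
    fit <- nmf_mu_cpp(M, W0, C0, max_iter, tol, TRUE, FALSE)
    restart_sse[r] <- fit$residual_sse
    if (is.null(best) || fit$residual_sse < best$residual_sse) {
      best <- fit
    }
  }
  norm <- normalize_decomposition(best$W, best$C)
  ord <- activation_order(norm$C)
  W <- norm$W[, ord, drop = FALSE]
  C <- norm$C[ord, , drop = FALSE]
  rownames(W) <- rownames(M)
  structure(
    list(W = W, C = C, residual_sse = best$residual_sse, N = N,
         converged = best$converged, iterations = best$iterations,
         seed = as.integer(seed), restart_sse = restart_sse),
    class = "synergy_decomposition")
}

#' @export
print.synergy_decomposition <- function(x, ...) {
  cat(sprintf(
    "Synergy decomposition: N = %d, residual SSE = %.4g (%s in %d iterations)\n",
    x$N, x$residual_sse,
    if (x$converged) "converged" else "iteration cap reached",
    x$iterations))
  invisible(x)
}

#' Refit activations with fixed weightings
#'
#' Runs multiplicative updates on the activation matrix only, leaving the
#' supplied weightings untouched.  This is the held-out step of the
#' cross-validation: weightings learned on the training cycles are applied
#' to the test cycles.  The update from the deterministic
#' `t(W) %*% M`-based start converges to a local minimum of the convex
#' (given `W`) objective.
#'
#' @param M Non-negative matrix, muscles x time.
#' @param W Fixed non-negative weightings, muscles x N.
#' @param max_iter Iteration cap (default 1000).
#' @param tol Relative residual decrease stopping tolerance (default 1e-8).
#' @return Non-negative N x time activation matrix.
#' @export
fit_activations_fixed_w <- function(M, W, max_iter = 1000L, tol = 1e-8) {
  if (inherits(M, "cycle_matrix")) M <- M$values
  stop_if_not_matrix(M)
  stop_if_negative(M)
  stop_if_not_matrix(W)
  stop_if_negative(W)
  if (nrow(W) != nrow(M)) {
    stop("W and M must have the same number of muscles", call. = FALSE)
  }
  C0 <- pmax(crossprod(W, M), 1e-6)
  fit <- nmf_mu_cpp(M, W, C0, max_iter, tol, FALSE, FALSE)
  fit$C
}

# Residual trace of a single multiplicative-update run; exposed for
# monotone-descent diagnostics.
nmf_sse_trace <- function(M, N, seed = 1L, max_iter = 200L) {
  set.seed(as.integer(seed))
  m <- nrow(M); tt <- ncol(M)
  scale <- sqrt(max(mean(M), 1e-12) / N)
  W0 <- matrix(pmax(runif(m * N), 1e-6) * scale, m, N)
  C0 <- matrix(pmax(runif(N * tt), 1e-6) * scale, N, tt)
  nmf_mu_cpp(M, W0, C0, max_iter, -1, TRUE, TRUE)$sse_trace
}
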