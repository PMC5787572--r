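# Grouping of corresponding synergies across subjects and speeds by cosine
# similarity to a reference set, with duplicate resolution and one round of
# reference averaging.

#' Cosine similarity of two non-negative vectors
#'
#' @param u,v Non-zero numeric vectors of equal length.
#' @return `sum(u * v) / (|u| * |v|)`; in `[0, 1]` for non-negative input.
#' @export
cosine_sim <- function(u, v) {
  if (length(u) != length(v)) {
    stop("vectors must have equal length", call. = FALSE)
  }
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu <= 0 || nv <= 0) stop("zero vector", call. = FALSE)
  sum(u * v) / (nu * nv)
}

#' Critical correlation behind the 0.71 grouping threshold
#'
#' Two-tailed critical value of the Pearson correlation at significance
#' `alpha` for vectors of length `n` (df = n - 2):
#' `r = t / sqrt(t^2 + df)` with `t = qt(1 - alpha/2, df)`.  For the
#' 12-muscle weighting vectors at alpha = 0.01 this is 0.708, i.e. the
#' conventional 0.71 similarity cutoff.
#'
#' @param n Vector length (default 12 muscles).
#' @param alpha Two-tailed significance level (default 0.01).
#' @return Critical correlation in (0, 1).
#' @export
critical_similarity <- function(n = 12L, alpha = 0.01) {
  df <- n - 2L
  if (df < 1L) stop("n must be at least 3", call. = FALSE)
  tcrit <- qt(1 - alpha / 2, df)
  tcrit / sqrt(tcrit^2 + df)
}

# A synergy set: weightings W (muscles x k) and optionally C templates
# (k x bins, cycle-averaged activations).
check_synergy_set <- function(x, name) {
  if (!is.list(x) || is.null(x$W)) {
    stop(sprintf("'%s' must be a list with a weighting matrix 'W'", name),
         call. = FALSE)
  }
  stop_if_not_matrix(x$W, name)
  invisible(x)
}

# Cycle-average an activation matrix (k x (bins * cycles)) to k x bins.
activation_template <- function(C, n_bins = 100L) {
  t(apply(C, 1, function(row) {
    if (length(row) %% n_bins == 0L) rowMeans(matrix(row, n_bins))
    else row
  }))
}

#' Match candidate synergies to a reference set
#'
#' Computes the cosine similarity of weighting vectors (and, when both
#' sides carry them, of cycle-averaged activation templates) between every
#' candidate and every reference synergy.  A candidate is eligible for a
#' group when its W *or* C similarity exceeds `threshold`.  Groups are
#' claimed greedily by descending similarity, so when two candidates claim
#' the same group the higher-similarity pair wins and the loser falls back
#' to its next-best passing group or stays unmatched.  The result is
#' deterministic and invariant to candidate ordering.
#'
#' @param candidates,reference Lists with `W` (muscles x k matrix) and
#'   optional `C` (k x bins activation templates, rows matching `W`
#'   columns).
#' @param threshold Similarity cutoff (default 0.71; see
#'   [critical_similarity()]).
#' @return Data frame with one row per candidate synergy: `candidate`,
#'   `group` (reference index, `NA` if unmatched), `similarity`,
#'   `matched_on` ("W", "C" or `NA`).
#' @export
match_to_reference <- function(candidates, reference, threshold = 0.71) {
  check_synergy_set(candidates, "candidates")
  check_synergy_set(reference, "reference")
  nc <- ncol(candidates$W); nr <- ncol(reference$W)
  sim_w <- matrix(NA_real_, nc, nr)
  for (i in seq_len(nc)) for (j in seq_len(nr)) {
    sim_w[i, j] <- cosine_sim(candidates$W[, i], reference$W[, j])
  }
  sim_c <- matrix(-Inf, nc, nr)
  if (!is.null(candidates$C) && !is.null(reference$C)) {
    for (i in seq_len(nc)) for (j in seq_len(nr)) {
      sim_c[i, j] <- cosine_sim(candidates$C[i, ], reference$C[j, ])
    }
  }
  eligible <- sim_w > threshold | sim_c > threshold
  score <- pmax(sim_w, sim_c)

  out <- data.frame(candidate = seq_len(nc), group = NA_integer_,
                    similarity = NA_real_, matched_on = NA_character_)
  open <- eligible
  while (any(open)) {
    masked <- ifelse(open, score, -Inf)
    best <- which(masked == max(masked), arr.ind = TRUE)
    # deterministic tie-break: lowest group, then lowest candidate index
    best <- best[order(best[, 2], best[, 1]), , drop = FALSE][1, ]
    i <- best[1]; j <- best[2]
    out$group[i] <- j
    out$similarity[i] <- score[i, j]
    out$matched_on[i] <- if (sim_w[i, j] > threshold) "W" else "C"
    open[i, ] <- FALSE
    open[, j] <- FALSE
  }
  out
}

#' Average matched synergies into a refined reference
#'
#' Each group's template becomes the unit-norm mean of its members'
#' weighting vectors (and the mean of their activation templates); groups
#' with no members keep their original template.
#'
#' @param candidate_sets List of candidate synergy sets (as in
#'   [match_to_reference()]).
#' @param assignments List of assignment data frames, one per candidate
#'   set, from [match_to_reference()].
#' @param reference The original reference set.
#' @return A synergy set with averaged `W` (and `C` when available).
#' @export
refine_reference <- function(candidate_sets, assignments, reference) {
  check_synergy_set(reference, "reference")
  nr <- ncol(reference$W)
  W_new <- reference$W
  C_new <- reference$C
  for (j in seq_len(nr)) {
    ws <- list(); cs <- list()
    for (s in seq_along(candidate_sets)) {
      a <- assignments[[s]]
      hit <- which(a$group == j)
      if (length(hit) == 1L) {
        ws[[length(ws) + 1L]] <- candidate_sets[[s]]$W[, a$candidate[hit]]
        if (!is.null(candidate_sets[[s]]$C) && !is.null(C_new)) {
          cs[[length(cs) + 1L]] <- candidate_sets[[s]]$C[a$candidate[hit], ]
        }
      }
    }
    if (length(ws)) {
      wbar <- rowMeans(do.call(cbind, ws))
      W_new[, j] <- wbar / sqrt(sum(wbar^2))
      if (length(cs)) C_new[j, ] <- rowMeans(do.call(cbind, cs))
    }
  }
  out <- list(W = W_new)
  if (!is.null(C_new)) out$C <- C_new
  out
}

#' Group synergies across subjects against one reference subject
#'
#' Initial matching of every subject's synergies to an arbitrary reference
#' subject's, then one refinement pass: group templates are averaged over
#' the matched members and matching is re-run against the averages.
#'
#' @param sets Named list of synergy sets, one per (subject, speed)
#'   decomposition; each with `W` and optional `C` templates.
#' @param reference_index Which element of `sets` seeds the groups
#'   (default 1).
#' @param threshold Similarity cutoff (default 0.71).
#' @return An object of class `synergy_grouping`: `reference` (averaged
#'   templates), `assignments` (one data frame per set) and `threshold`.
#' @export
group_synergies <- function(sets, reference_index = 1L, threshold = 0.71) {
  stopifnot(length(sets) >= 1L)
  reference <- sets[[reference_index]]
  first <- lapply(sets, match_to_reference, reference = reference,
                  threshold = threshold)
  averaged <- refine_reference(sets, first, reference)
  final <- lapply(sets, match_to_reference, reference = averaged,
                  threshold = threshold)
  structure(
    list(reference = averaged, assignments = final,
         threshold = threshold),
    class = "synergy_grouping")
}

#' @export
print.synergy_grouping <- function(x, ...) {
  n_tot <- sum(vapply(x$assignments, nrow, integer(1)))
  n_hit <- sum(vapply(x$assignments,
                      function(a) sum(!is.na(a$group)), integer(1)))
  cat(sprintf(
    "Synergy grouping: %d/%d synergies assigned to %d groups (threshold %.2f)\n",
    n_hit, n_tot, ncol(x$reference$W), x$threshold))
  invisible(x)
}
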