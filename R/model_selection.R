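#' Total within-cluster sum of squares
#'
#' `sum over clusters c, bins i in c, channels j of (O_ij - mean_cj)^2`,
#' the elbow-curve statistic for choosing the number of states. An empty
#' cluster contributes 0.
#'
#' @param signals a `signal_matrix` (only usable bins enter).
#' @param labels integer cluster labels, one per usable bin.
#' @return the within-cluster sum of squares.
#' @export
within_cluster_ss <- function(signals, labels) {
  stopifnot(inherits(signals, "signal_matrix"))
  x <- signals$matrix[signals$mask, , drop = FALSE]
  stopifnot(length(labels) == nrow(x))
  wss <- 0
  for (h in unique(labels)) {
    xs <- x[labels == h, , drop = FALSE]
    wss <- wss + sum(sweep(xs, 2, colMeans(xs))^2)
  }
  wss
}

#' Akaike and Bayesian information criteria
#'
#' `AIC = -2 ln(L) + 2K` and `BIC = -2 ln(L) + K ln(n)`.
#'
#' @param log_l log-likelihood (for the HMRF this is the sum over nodes of
#'   the log belief of the predicted state).
#' @param k_params number of free parameters K.
#' @param n number of nodes.
#' @return named numeric vector `c(AIC = ..., BIC = ...)`.
#' @export
aic_bic <- function(log_l, k_params, n) {
  stopifnot(n >= 1, k_params >= 0)
  c(AIC = -2 * log_l + 2 * k_params,
    BIC = -2 * log_l + k_params * log(n))
}

# internal: free-parameter count of a k-state, d-channel model:
# means + full covariances + symmetric normalized compatibility + mixture
.param_count <- function(k, d) {
  k * d + k * d * (d + 1) / 2 + k * (k - 1) / 2 + (k - 1)
}

# internal: elbow of a score curve. A curve is "informative" when it is
# predominantly decreasing (total drop >= 70% of total variation). The
# elbow is the smallest k from which every remaining per-step drop is
# small -- at most `frac` of the mean per-step drop accumulated before k.
# Comparing against the mean preceding drop (rather than the first drop
# alone) keeps the rule invariant to how large the between-state variance
# is relative to the within-state floor, and tolerant of one noisy
# restart late in the curve.
.curve_elbow <- function(ks, score, frac = 0.2) {
  ok <- is.finite(score)
  ks <- ks[ok]; score <- score[ok]
  if (length(ks) < 3) return(list(informative = FALSE, elbow = NA_integer_))
  drops <- -diff(score)                 # drop of the step ks[i] -> ks[i+1]
  drop_total <- score[1] - min(score)
  variation <- sum(abs(drops))
  informative <- variation > 0 && drop_total / variation >= 0.7 &&
    drops[1] > 0
  if (!informative) return(list(informative = FALSE, elbow = NA_integer_))
  m <- length(drops)
  elbow <- ks[length(ks)]
  for (i in 2:m) {
    if (max(drops[i:m]) <= frac * mean(drops[1:(i - 1)])) {
      elbow <- ks[i]
      break
    }
  }
  list(informative = TRUE, elbow = elbow)
}

#' Choose the number of states
#'
#' For each candidate `k`, computes (1) the k-means elbow statistic
#' (best-of-`nstart` restarts within-cluster sum of squares) and (2) the
#' AIC/BIC of a fitted HMRF, with the log likelihood taken as the sum of
#' log beliefs of the predicted states. The recommended `k` is the
#' smallest candidate after which every informative score curve (WSS, and
#' AIC/BIC when they actually improve with `k`) has flattened: all
#' remaining per-step drops at most `slope_frac` (default 20%) of the mean
#' per-step drop accumulated before that candidate. The full score table
#' is always returned so the user can override.
#'
#' @param signals a `signal_matrix`.
#' @param graph an `interaction_graph`.
#' @param k_range candidate state numbers (default 2:15).
#' @param seed integer seed.
#' @param slope_frac flattening threshold as a fraction of the mean
#'   preceding per-step drop.
#' @param nstart k-means restarts for the elbow curve.
#' @param ... further arguments passed to [spin_fit()] (e.g. `em_max_iter`).
#' @return a `selection_scores` object: `table` (data.frame with k, WSS,
#'   logL, K, AIC, BIC), `recommended_k`, and the per-curve elbows.
#' @export
select_k <- function(signals, graph, k_range = 2:15, seed = 1,
                     slope_frac = 0.2, nstart = 10, ...) {
  stopifnot(inherits(signals, "signal_matrix"), length(k_range) >= 1)
  x <- signals$matrix[signals$mask, , drop = FALSE]
  d <- ncol(x)
  n <- length(graph$nodes)
  rows <- lapply(k_range, function(k) {
    wss <- tryCatch({
      set.seed(seed + k)
      if (k < nrow(unique(x))) {
        km <- stats::kmeans(x, centers = k, nstart = nstart,
                            iter.max = 100)
        km$tot.withinss
      } else 0
    }, error = function(e) NA_real_)
    res <- tryCatch({
      ft <- spin_fit(signals, graph, k = k, seed = seed, ...)
      logl <- sum(log(pmax(ft$assignment$max_belief, 1e-300)))
      ab <- aic_bic(logl, .param_count(k, d), n)
      c(logl, ab)
    }, error = function(e) {
      warning("fit failed for k = ", k, ": ", conditionMessage(e))
      c(NA_real_, NA_real_, NA_real_)
    })
    data.frame(k = k, WSS = wss, logL = res[1],
               K = .param_count(k, d), AIC = res[2], BIC = res[3])
  })
  tab <- do.call(rbind, rows)
  elbows <- list(WSS = .curve_elbow(tab$k, tab$WSS, slope_frac),
                 AIC = .curve_elbow(tab$k, tab$AIC, slope_frac),
                 BIC = .curve_elbow(tab$k, tab$BIC, slope_frac))
  informative <- Filter(function(e) e$informative, elbows)
  recommended <- if (length(k_range) == 1) k_range
                 else if (length(informative))
                   max(vapply(informative, `[[`, 0L, "elbow"))
                 else min(k_range)
  structure(list(table = tab, recommended_k = as.integer(recommended),
                 elbows = elbows),
            class = "selection_scores")
}

#' @export
print.selection_scores <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat("recommended k:", x$recommended_k, "\n")
  invisible(x)
}
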