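# internal: Hungarian algorithm (Jonker/e-maxx potentials formulation) for a
# square cost matrix; returns assignment col -> row minimizing total cost
.hungarian <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1); way <- integer(n + 1)   # index 1 = dummy column 0
  for (i in seq_len(n)) {
    p[1] <- i; j0 <- 0L
    minv <- rep(Inf, n + 1); used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]; delta <- Inf; j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1L]) {
          cur <- cost[i0, j] - u[i0 + 1L] - v[j + 1L]
          if (cur < minv[j + 1L]) { minv[j + 1L] <- cur; way[j + 1L] <- j0 }
          if (minv[j + 1L] < delta) { delta <- minv[j + 1L]; j1 <- j }
        }
      }
      for (j in 0:n) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  p[-1]                                  # p[j] = row assigned to column j
}

#' Permutation-invariant label matching
#'
#' Matches predicted cluster labels to reference labels by maximizing the
#' number of agreeing bins over all one-to-one state matchings (solved with
#' the Hungarian algorithm on the confusion matrix), and reports the
#' resulting accuracy. This is the standard way to score a segmentation
#' against a planted truth whose state numbering is arbitrary.
#'
#' @param truth,pred integer label vectors of equal length.
#' @param k number of states (default: largest label seen).
#' @return list with `map` (integer vector: `map[pred_label]` = matched
#'   truth label), `accuracy` (fraction of bins agreeing after matching)
#'   and the `confusion` matrix (truth x pred).
#' @export
match_labels <- function(truth, pred, k = max(c(truth, pred))) {
  stopifnot(length(truth) == length(pred))
  conf <- table(factor(truth, levels = 1:k), factor(pred, levels = 1:k))
  conf <- unclass(conf)
  assign_rows <- .hungarian(max(conf) - conf)   # col (pred) -> row (truth)
  acc <- sum(conf[cbind(assign_rows, 1:k)]) / length(truth)
  list(map = assign_rows, accuracy = acc, confusion = conf)
}

# internal: coefficient of determination
.r_squared <- function(y, yhat) {
  sst <- sum((y - mean(y))^2)
  if (sst == 0) return(NA_real_)
  1 - sum((y - yhat)^2) / sst
}
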