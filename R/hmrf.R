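#' Hidden Markov random field model container
#'
#' Parameters of the compartmentalization HMRF: `k` hidden states with
#' multivariate Gaussian emissions (mean vector and full covariance per
#' state), a symmetric state-compatibility ("transition") matrix with rows
#' normalized to sum to 1, and mixture proportions.
#'
#' @param means k x d matrix of state means.
#' @param covariances d x d x k array of state covariances.
#' @param transition k x k nonnegative matrix; stored after symmetric
#'   (Sinkhorn-style) normalization so it is both symmetric and
#'   row-stochastic.
#' @param mixture length-k proportions (default uniform).
#' @param channels optional channel names (length d).
#' @return an `hmrf_model` object.
#' @export
hmrf_model <- function(means, covariances, transition, mixture = NULL,
                       channels = NULL) {
  means <- as.matrix(means)
  k <- nrow(means); d <- ncol(means)
  stopifnot(length(dim(covariances)) == 3,
            dim(covariances)[1] == d, dim(covariances)[2] == d,
            dim(covariances)[3] == k,
            nrow(transition) == k, ncol(transition) == k,
            all(transition >= 0))
  if (is.null(mixture)) mixture <- rep(1 / k, k)
  stopifnot(length(mixture) == k, all(mixture >= 0))
  mixture <- mixture / sum(mixture)
  if (is.null(channels)) channels <- colnames(means)
  structure(list(k = k, d = d, means = means, covariances = covariances,
                 transition = transition, mixture = mixture,
                 channels = channels),
            class = "hmrf_model")
}

#' @export
print.hmrf_model <- function(x, ...) {
  cat(sprintf("hmrf_model: k = %d states, d = %d channels\n", x$k, x$d))
  invisible(x)
}

# internal: log-sum-exp over rows of a matrix
.logsumexp_rows <- function(m) {
  mx <- do.call(pmax, as.data.frame(m))
  mx[!is.finite(mx)] <- 0
  log(rowSums(exp(m - mx))) + mx
}

# internal: symmetric Sinkhorn-style normalization; returns a symmetric
# nonnegative matrix whose rows sum to 1 (up to tolerance)
.sym_row_normalize <- function(w, floor_delta = 1e-6, max_iter = 5000,
                               tol = 1e-12) {
  w <- (w + t(w)) / 2
  zero_rows <- rowSums(w) <= 0
  if (any(zero_rows)) {
    # a state with no incident mass: smooth its row/column with a floor
    w[zero_rows, ] <- w[zero_rows, ] + floor_delta
    w[, zero_rows] <- w[, zero_rows] + floor_delta
  }
  # keep the scaling problem in the interior so the fixed point exists
  w <- pmax(w, 1e-8 * max(w))
  # diagonal scaling x with x * (W x) = 1 makes diag(x) W diag(x) symmetric
  # and row-stochastic; Sinkhorn-style sweeps, then a Newton polish for
  # matrices whose fixed point sits near the boundary
  x <- 1 / sqrt(rowSums(w))
  for (it in seq_len(max_iter)) {
    r <- x * (w %*% x)[, 1]
    if (max(abs(r - 1)) < tol) break
    x <- x / sqrt(r)
    if (it > 50 && it %% 10 == 0) {
      jac <- diag((w %*% x)[, 1]) + x * w
      step <- tryCatch(solve(jac, r - 1), error = function(e) NULL)
      if (!is.null(step)) x <- pmax(x - step, 1e-12)
    }
  }
  w <- w * outer(x, x)
  (w + t(w)) / 2
}

#' Multivariate Gaussian log density
#'
#' Exact log density of a d-dimensional Gaussian, evaluated via the Cholesky
#' factor of the (optionally ridge-regularized) covariance.
#'
#' @param obs observation vector of length d, or an n x d matrix of
#'   observations (one log density per row).
#' @param mean length-d mean vector.
#' @param cov d x d covariance matrix.
#' @param ridge nonnegative value added to the diagonal before
#'   factorization.
#' @return numeric log density (vector of length n for matrix input).
#' @export
gaussian_log_density <- function(obs, mean, cov, ridge = 0) {
  x <- if (is.matrix(obs)) obs else matrix(obs, nrow = 1)
  d <- length(mean)
  stopifnot(ncol(x) == d, nrow(cov) == d, ncol(cov) == d)
  s <- cov + diag(ridge, d)
  ch <- tryCatch(chol(s), error = function(e) NULL)
  if (is.null(ch))
    stop("covariance is not positive-definite after ridge regularization")
  centered <- sweep(x, 2, mean)
  z <- backsolve(ch, t(centered), transpose = TRUE)    # solves L z = x - mu
  quad <- colSums(z^2)
  ld <- -0.5 * (d * log(2 * pi) + 2 * sum(log(diag(ch))) + quad)
  if (is.matrix(obs)) ld else ld[1]
}

# internal: n x k matrix of per-state emission log densities
.emission_log_density <- function(x, model) {
  m <- vapply(seq_len(model$k), function(h)
    gaussian_log_density(x, model$means[h, ], model$covariances[, , h]),
    numeric(nrow(x)))
  matrix(m, nrow = nrow(x), ncol = model$k)
}

# internal: covariance ridge epsilon = factor * trace / d
.cov_ridge <- function(s, factor = 1e-6) factor * sum(diag(s)) / nrow(s)

# internal: apply the ridge to every state covariance of a model
.ridge_covariances <- function(covs, factor = 1e-6) {
  for (h in seq_len(dim(covs)[3])) {
    s <- covs[, , h]
    covs[, , h] <- s + diag(.cov_ridge(s, factor), nrow(s))
  }
  covs
}

#' Gaussian-mixture initialization of the HMRF
#'
#' Fits a k-component full-covariance Gaussian mixture to the usable
#' observation vectors (EM, via \pkg{mclust}) and takes per-bin maximum
#' a posteriori component labels as the initial states. Falls back to
#' seeded k-means moments when the mixture fit fails; an empty component in
#' the fallback is reseeded from the point farthest from its center (the
#' event is reported via `message()`).
#'
#' @param signals a `signal_matrix`.
#' @param k number of states.
#' @param seed integer seed; the result is deterministic given the seed.
#' @param nodes optional 0-based bin indices to fit on (default: all usable
#'   bins).
#' @param ridge_factor covariance ridge factor.
#' @return list with `model` (an `hmrf_model` without a transition yet:
#'   transition set to uniform) and `labels` (1..k per node).
#' @export
gmm_initialize <- function(signals, k, seed = 1, nodes = NULL,
                           ridge_factor = 1e-6) {
  stopifnot(inherits(signals, "signal_matrix"), k >= 1)
  if (is.null(nodes)) nodes <- which(signals$mask) - 1L
  x <- signals$matrix[nodes + 1L, , drop = FALSE]
  d <- ncol(x)
  if (nrow(x) < k * (d + 1))
    stop("need at least k*(d+1) = ", k * (d + 1), " usable bins, got ",
         nrow(x))
  set.seed(seed)
  if (k == 1) {
    mu <- matrix(colMeans(x), 1, d)
    covs <- array(stats::cov(x), dim = c(d, d, 1))
    labels <- rep(1L, nrow(x))
    pro <- 1
  } else {
    mc <- tryCatch(
      mclust::Mclust(x, G = k, modelNames = "VVV", verbose = FALSE),
      error = function(e) NULL)
    if (!is.null(mc) && !is.null(mc$parameters)) {
      mu <- t(mc$parameters$mean)
      covs <- mc$parameters$variance$sigma
      pro <- mc$parameters$pro
      labels <- max.col(mc$z, ties.method = "first")
    } else {
      km <- stats::kmeans(x, centers = k, nstart = 10, iter.max = 100)
      labels <- km$cluster
      for (h in seq_len(k)) {
        if (!any(labels == h)) {
          message("empty mixture component ", h,
                  "; reseeded from the farthest point")
          cent <- km$centers[labels, , drop = FALSE]
          far <- which.max(rowSums((x - cent)^2))
          labels[far] <- h
        }
      }
      mu <- matrix(0, k, d)
      covs <- array(0, dim = c(d, d, k))
      for (h in seq_len(k)) {
        xs <- x[labels == h, , drop = FALSE]
        mu[h, ] <- colMeans(xs)
        covs[, , h] <- if (nrow(xs) > d) stats::cov(xs) else diag(d)
      }
      pro <- tabulate(labels, k) / length(labels)
    }
  }
  covs <- .ridge_covariances(covs, ridge_factor)
  colnames(mu) <- signals$channels
  model <- hmrf_model(mu, covs, transition = matrix(1 / k, k, k),
                      mixture = pro, channels = signals$channels)
  list(model = model, labels = as.integer(labels), nodes = nodes)
}

#' Initial state-compatibility matrix from hard labels
#'
#' Counts label co-occurrence over the graph edges: the raw entry for
#' states (a, b) is the number of edges joining an a-labeled and a
#' b-labeled node (each undirected edge contributing both orientations to
#' the numerator) divided by the number of edge endpoints carrying label a
#' on the first endpoint or label b on the second. The raw matrix is then
#' symmetrized and projected to the symmetric row-stochastic scale used as
#' the edge potential; the un-normalized raw matrix is kept in the
#' `"raw"` attribute.
#'
#' @param labels integer states (1..k), one per graph node.
#' @param graph an `interaction_graph`.
#' @param k number of states (default `max(labels)`).
#' @param floor_delta smoothing floor for states with no incident edges.
#' @return k x k symmetric row-stochastic matrix with attribute `"raw"`.
#' @export
initial_transition <- function(labels, graph, k = max(labels),
                               floor_delta = 1e-6) {
  stopifnot(inherits(graph, "interaction_graph"),
            length(labels) == length(graph$nodes))
  pos <- match(graph$edges$i, graph$nodes)
  qos <- match(graph$edges$j, graph$nodes)
  la <- labels[pos]; lb <- labels[qos]
  num <- matrix(0, k, k)
  cnt <- table(factor(la, levels = 1:k), factor(lb, levels = 1:k))
  num <- unclass(cnt) + t(unclass(cnt))       # both orientations
  ends_first <- tabulate(la, k)               # label counts on first endpoint
  ends_second <- tabulate(lb, k)
  den <- outer(ends_first, rep(1, k)) + outer(rep(1, k), ends_second)
  raw <- ifelse(den > 0, num / den, 0)
  t_mat <- .sym_row_normalize(raw, floor_delta = floor_delta)
  attr(t_mat, "raw") <- raw
  t_mat
}

#' Loopy belief propagation on the interaction graph
#'
#' Approximates per-node marginal state probabilities by synchronous
#' ("flooding") message passing: every directed message is updated
#' simultaneously from the previous iteration's incoming messages, using the
#' Gaussian node potential, the state-compatibility edge potential, and the
#' product of incoming messages excluding the recipient. Messages are
#' normalized to sum to 1; all computation is in log space. Iteration stops
#' when the largest absolute belief change falls below `tol` or after
#' `max_iter` sweeps.
#'
#' @param model an `hmrf_model`.
#' @param graph an `interaction_graph`.
#' @param signals a `signal_matrix` covering the graph nodes.
#' @param max_iter maximum sweeps (default 500).
#' @param tol convergence tolerance on the probability-scale belief change.
#' @param damping optional damping factor in `[0, 1)` applied in log space
#'   (0 = plain synchronous updates).
#' @param use_mixture_weights add `log(pi)` of the mixture proportions to
#'   the node potential (the mixture-consistent convention; default TRUE).
#' @param init_messages optional log-message matrix from a previous run
#'   (warm start); default: uniform messages ("all set to 1", normalized).
#' @return a `belief_state`: `log_beliefs` (nodes x k), `log_messages`
#'   (directed edges x k), `iterations`, `converged`, plus the node and
#'   directed-edge bookkeeping.
#' @export
lbp_infer <- function(model, graph, signals, max_iter = 500L, tol = 1e-6,
                      damping = 0, use_mixture_weights = TRUE,
                      init_messages = NULL) {
  stopifnot(inherits(model, "hmrf_model"),
            inherits(graph, "interaction_graph"),
            inherits(signals, "signal_matrix"),
            damping >= 0, damping < 1)
  nodes <- graph$nodes
  n <- length(nodes); k <- model$k
  x <- signals$matrix[nodes + 1L, , drop = FALSE]
  if (anyNA(x)) stop("signals contain missing values on graph nodes")
  np <- .emission_log_density(x, model)
  if (use_mixture_weights)
    np <- sweep(np, 2, log(pmax(model$mixture, 1e-300)), "+")

  m_edges <- nrow(graph$edges)
  src <- c(match(graph$edges$i, nodes), match(graph$edges$j, nodes))
  dst <- c(match(graph$edges$j, nodes), match(graph$edges$i, nodes))
  rev_idx <- c(m_edges + seq_len(m_edges), seq_len(m_edges))

  msg <- if (is.null(init_messages)) matrix(-log(k), 2 * m_edges, k)
         else init_messages
  t_exp <- model$transition

  agg_incoming <- function(msg) {
    s <- matrix(0, n, k)
    if (nrow(msg)) {
      rs <- rowsum(msg, group = dst)
      s[as.integer(rownames(rs)), ] <- rs
    }
    s
  }

  beliefs_prob <- NULL
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    if (m_edges > 0) {
      s <- agg_incoming(msg)
      pre <- np[src, , drop = FALSE] + s[src, , drop = FALSE] -
        msg[rev_idx, , drop = FALSE]
      mx <- do.call(pmax, as.data.frame(pre))
      mx[!is.finite(mx)] <- 0
      new_msg <- log(exp(pre - mx) %*% t_exp) + mx
      new_msg <- new_msg - .logsumexp_rows(new_msg)
      if (anyNA(new_msg) || any(!is.finite(.logsumexp_rows(new_msg)))) {
        bad <- which(apply(new_msg, 1, function(r) anyNA(r) ||
                             all(!is.finite(r))))[1]
        stop("non-finite message on directed edge ",
             nodes[src[bad]], " -> ", nodes[dst[bad]])
      }
      msg <- if (damping > 0) (1 - damping) * new_msg + damping * msg
             else new_msg
    }
    b <- np + agg_incoming(msg)
    b <- b - .logsumexp_rows(b)
    bp <- exp(b)
    if (!is.null(beliefs_prob) &&
        max(abs(bp - beliefs_prob)) < tol) {
      beliefs_prob <- bp; log_beliefs <- b; converged <- TRUE
      break
    }
    beliefs_prob <- bp; log_beliefs <- b
    if (m_edges == 0) { converged <- TRUE; break }
  }
  structure(list(log_messages = msg, log_beliefs = log_beliefs,
                 nodes = nodes, src = src, dst = dst,
                 iterations = iter, converged = converged),
            class = "belief_state")
}

#' Mean-field E-step posteriors
#'
#' Per-node state posterior combining the Gaussian emission with the
#' neighbor term of the mean-field factorization:
#' `P(H_i = a | O_i, N(i))` is proportional to `P(O_i | H_i = a)` times the
#' product over neighbors `j` of `t(a, h_j)`, where `h_j` is the current
#' hard state estimate of neighbor `j` (from belief propagation).
#'
#' @param model an `hmrf_model`.
#' @param graph an `interaction_graph`.
#' @param signals a `signal_matrix`.
#' @param hard_states integer states (1..k), one per graph node.
#' @return nodes x k matrix of posteriors (rows sum to 1).
#' @export
estep_posteriors <- function(model, graph, signals, hard_states) {
  nodes <- graph$nodes
  n <- length(nodes); k <- model$k
  stopifnot(length(hard_states) == n)
  x <- signals$matrix[nodes + 1L, , drop = FALSE]
  emis <- .emission_log_density(x, model)
  logt <- log(pmax(model$transition, 1e-300))
  contrib <- matrix(0, n, k)
  if (nrow(graph$edges)) {
    src <- c(match(graph$edges$i, nodes), match(graph$edges$j, nodes))
    dst <- c(match(graph$edges$j, nodes), match(graph$edges$i, nodes))
    lmat <- t(logt)[hard_states[src], , drop = FALSE]  # row e: logt[, h_src]
    rs <- rowsum(lmat, group = dst)
    contrib[as.integer(rownames(rs)), ] <- rs
  }
  lp <- emis + contrib
  post <- exp(lp - .logsumexp_rows(lp))
  post / rowSums(post)
}

#' Mean-field M-step parameter update
#'
#' Given per-node posteriors, updates state means and covariances as
#' posterior-weighted sample moments, the mixture as the mean posterior,
#' and the state-compatibility matrix from the expected edge co-occurrence
#' counts `sum over edges of q_i(a) q_j(b)` (both orientations),
#' symmetrized and renormalized. A state whose total posterior weight falls
#' below `d + 1` keeps its previous covariance (with a warning).
#'
#' @param posteriors nodes x k posterior matrix (rows sum to 1).
#' @param signals a `signal_matrix`.
#' @param graph an `interaction_graph`.
#' @param prev_model the current `hmrf_model` (source of fallback
#'   covariances).
#' @param ridge_factor covariance ridge factor.
#' @return an updated `hmrf_model`.
#' @export
mstep_update <- function(posteriors, signals, graph, prev_model,
                         ridge_factor = 1e-6) {
  nodes <- graph$nodes
  q <- as.matrix(posteriors)
  n <- nrow(q); k <- ncol(q)
  stopifnot(length(nodes) == n)
  x <- signals$matrix[nodes + 1L, , drop = FALSE]
  d <- ncol(x)
  w <- colSums(q)
  mixture <- w / n
  means <- sweep(crossprod(q, x), 1, pmax(w, 1e-12), "/")
  covs <- array(0, dim = c(d, d, k))
  low_weight <- w < (d + 1)
  for (h in seq_len(k)) {
    if (low_weight[h]) {
      covs[, , h] <- prev_model$covariances[, , h]
    } else {
      xc <- sweep(x, 2, means[h, ])
      s <- crossprod(xc * q[, h], xc) / w[h]
      covs[, , h] <- s + diag(.cov_ridge(s, ridge_factor), d)
    }
  }
  if (any(low_weight))
    warning("state(s) ", paste(which(low_weight), collapse = ", "),
            " with total weight < d+1: covariance kept from previous ",
            "iteration")
  pos <- match(graph$edges$i, nodes)
  qos <- match(graph$edges$j, nodes)
  cooc <- crossprod(q[pos, , drop = FALSE], q[qos, , drop = FALSE])
  trans <- .sym_row_normalize(cooc + t(cooc))
  colnames(means) <- prev_model$channels
  hmrf_model(means, covs, trans, mixture, channels = prev_model$channels)
}

#' Per-bin state assignment
#'
#' @param graph the `interaction_graph` the assignment lives on.
#' @param labels hard labels (1..k), one per graph node; ties in the
#'   underlying beliefs are broken toward the lowest state index.
#' @param beliefs nodes x k belief matrix (probability scale).
#' @return a `state_assignment` object.
#' @export
state_assignment <- function(graph, labels, beliefs) {
  stopifnot(inherits(graph, "interaction_graph"),
            length(labels) == length(graph$nodes),
            nrow(beliefs) == length(graph$nodes))
  structure(list(bins = graph$bins, nodes = graph$nodes,
                 labels = as.integer(labels), beliefs = beliefs,
                 max_belief = beliefs[cbind(seq_along(labels), labels)]),
            class = "state_assignment")
}

#' @export
print.state_assignment <- function(x, ...) {
  cat(sprintf("state_assignment: %d bins, %d states\n",
              length(x$nodes), ncol(x$beliefs)))
  print(table(state = x$labels))
  invisible(x)
}

#' Fit the compartmentalization HMRF
#'
#' Full estimation pipeline: Gaussian-mixture initialization of emissions
#' and labels, initial state-compatibility matrix from label co-occurrence
#' on the graph, then alternation of loopy belief propagation (inference),
#' the mean-field E-step, and the M-step parameter update, until fewer than
#' `em_tol` fraction of hard labels change between iterations (or
#' `em_max_iter` is reached). Deterministic given `seed`.
#'
#' @param signals a `signal_matrix`.
#' @param graph an `interaction_graph` on the same bins.
#' @param k number of states.
#' @param seed integer seed.
#' @param em_max_iter,em_tol EM loop controls (default: 30 iterations,
#'   stop when < 0.1% of labels change).
#' @param lbp_max_iter,lbp_tol,damping passed to [lbp_infer()].
#' @param use_mixture_weights see [lbp_infer()].
#' @param ridge_factor covariance ridge factor.
#' @param verbose print per-iteration label-change counts.
#' @return a `spin_fit` object: `model`, `assignment`, `beliefs`, and a
#'   `trace` of per-iteration label changes (`label_changes`, `converged`).
#' @export
spin_fit <- function(signals, graph, k, seed = 1,
                     em_max_iter = 30L, em_tol = 1e-3,
                     lbp_max_iter = 500L, lbp_tol = 1e-6, damping = 0,
                     use_mixture_weights = TRUE, ridge_factor = 1e-6,
                     verbose = FALSE) {
  stopifnot(inherits(signals, "signal_matrix"),
            inherits(graph, "interaction_graph"))
  if (!.same_bins(signals$bins, graph$bins))
    stop("signals and graph are on different bin frames")
  init <- gmm_initialize(signals, k, seed = seed, nodes = graph$nodes,
                         ridge_factor = ridge_factor)
  model <- init$model
  model$transition <- initial_transition(init$labels, graph, k = k)
  attr(model$transition, "raw") <- NULL

  labels <- NULL
  msgs <- NULL
  changes <- integer(0)
  converged <- FALSE
  bs <- NULL
  for (it in seq_len(em_max_iter)) {
    bs <- lbp_infer(model, graph, signals, max_iter = lbp_max_iter,
                    tol = lbp_tol, damping = damping,
                    use_mixture_weights = use_mixture_weights,
                    init_messages = msgs)
    msgs <- bs$log_messages
    new_labels <- max.col(bs$log_beliefs, ties.method = "first")
    if (!is.null(labels)) {
      frac <- mean(new_labels != labels)
      changes <- c(changes, sum(new_labels != labels))
      if (verbose)
        message(sprintf("EM iteration %d: %.3f%% labels changed",
                        it, 100 * frac))
      if (frac < em_tol) { labels <- new_labels; converged <- TRUE; break }
    }
    labels <- new_labels
    post <- estep_posteriors(model, graph, signals, labels)
    model <- mstep_update(post, signals, graph, model,
                          ridge_factor = ridge_factor)
  }
  beliefs <- exp(bs$log_beliefs)
  structure(list(model = model,
                 assignment = state_assignment(graph, labels, beliefs),
                 beliefs = bs,
                 trace = list(label_changes = changes,
                              converged = converged, seed = seed, k = k)),
            class = "spin_fit")
}

#' @export
print.spin_fit <- function(x, ...) {
  cat(sprintf("spin_fit: k = %d, EM %s after %d label updates\n",
              x$model$k,
              if (x$trace$converged) "converged" else "stopped",
              length(x$trace$label_changes) + 1L))
  invisible(x)
}

#' Rank states along the speckle axis
#'
#' Renumbers states 1..k by ascending mean of the named channel (1 = lowest
#' speckle signal, i.e. lamina-like; k = highest, speckle-like), giving
#' stable, interpretable labels across runs. Ties are broken by the next
#' channels in order, then by the original state index.
#'
#' @param model an `hmrf_model`.
#' @param speckle_channel channel name to rank on (e.g. `"SON_TSA"`).
#' @return integer vector `ranking` with `ranking[old_state] = new_label`.
#' @export
rank_states <- function(model, speckle_channel) {
  stopifnot(inherits(model, "hmrf_model"))
  ch <- match(speckle_channel, model$channels)
  if (is.na(ch)) stop("unknown channel: ", speckle_channel)
  keys <- c(list(model$means[, ch]),
            lapply(setdiff(seq_len(model$d), ch),
                   function(j) model$means[, j]),
            list(seq_len(model$k)))
  ord <- do.call(order, keys)
  ranking <- integer(model$k)
  ranking[ord] <- seq_len(model$k)
  ranking
}

#' Apply a state ranking to a fitted model and assignment
#'
#' @param fit a `spin_fit` object.
#' @param ranking permutation from [rank_states()].
#' @return the `spin_fit` with states relabeled (means, covariances,
#'   transition, mixture, labels, beliefs all permuted consistently).
#' @export
relabel_states <- function(fit, ranking) {
  stopifnot(inherits(fit, "spin_fit"),
            length(ranking) == fit$model$k)
  inv <- order(ranking)           # inv[new_label] = old_state
  m <- fit$model
  m$means <- m$means[inv, , drop = FALSE]
  m$covariances <- m$covariances[, , inv, drop = FALSE]
  m$transition <- m$transition[inv, inv]
  m$mixture <- m$mixture[inv]
  fit$model <- m
  fit$assignment$labels <- ranking[fit$assignment$labels]
  fit$assignment$beliefs <- fit$assignment$beliefs[, inv, drop = FALSE]
  fit$assignment$max_belief <-
    fit$assignment$beliefs[cbind(seq_along(fit$assignment$labels),
                                 fit$assignment$labels)]
  fit
}
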