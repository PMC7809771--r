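# Independent oracles used across the suite. These deliberately use naive,
# easily-audited computations (enumeration, double loops, dense algebra)
# rather than the package's own code paths.

# Exact marginals of an MRF by brute-force enumeration over all k^n
# configurations: P(H) ~ prod_i exp(np[i, H_i]) * prod_(i,j) T[H_i, H_j].
# np: n x k log node potentials; edges: data.frame(i, j) of 1-based node
# ids; t_mat: k x k edge potential.
enumerate_marginals <- function(np, edges, t_mat) {
  n <- nrow(np); k <- ncol(np)
  cfg <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
  lp <- numeric(nrow(cfg))
  for (i in seq_len(n)) lp <- lp + np[cbind(i, cfg[, i])]
  logt <- log(t_mat)
  if (nrow(edges)) {
    for (e in seq_len(nrow(edges)))
      lp <- lp + logt[cbind(cfg[, edges$i[e]], cfg[, edges$j[e]])]
  }
  w <- exp(lp - max(lp))
  marg <- matrix(0, n, k)
  for (i in seq_len(n))
    for (a in seq_len(k))
      marg[i, a] <- sum(w[cfg[, i] == a])
  marg / rowSums(marg)
}

# Random tree on n nodes (uniform attachment), returned as a 1-based edge
# list.
random_tree_edges <- function(n) {
  if (n < 2) return(data.frame(i = integer(), j = integer()))
  parent <- vapply(2:n, function(v) sample.int(v - 1L, 1), 1L)
  data.frame(i = parent, j = 2:n)
}

# Chain-HMM posterior decoding by log-space forward-backward, as an
# independent smoother to compare the HMRF against when all Hi-C edges are
# removed. emis: n x k emission log densities; trans: row-stochastic k x k;
# init: length-k prior.
hmm_posterior_decode <- function(emis, trans, init = NULL) {
  n <- nrow(emis); k <- ncol(emis)
  if (is.null(init)) init <- rep(1 / k, k)
  lt <- log(trans); li <- log(init)
  lse <- function(x) { m <- max(x); m + log(sum(exp(x - m))) }
  fw <- matrix(-Inf, n, k); bw <- matrix(0, n, k)
  fw[1, ] <- li + emis[1, ]
  for (t in 2:n)
    for (b in seq_len(k))
      fw[t, b] <- emis[t, b] + lse(fw[t - 1, ] + lt[, b])
  for (t in (n - 1):1)
    for (a in seq_len(k))
      bw[t, a] <- lse(lt[a, ] + emis[t + 1, ] + bw[t + 1, ])
  post <- fw + bw
  max.col(post, ties.method = "first")
}

# Naive dense multivariate normal log density (explicit inverse and
# determinant), as an oracle for the Cholesky-based implementation.
dense_mvn_logdens <- function(x, mu, sigma) {
  d <- length(mu)
  xc <- as.numeric(x - mu)
  -0.5 * (d * log(2 * pi) + log(det(sigma)) +
            t(xc) %*% solve(sigma) %*% xc)[1, 1]
}

# Best label accuracy over all permutations (feasible for small k), as an
# oracle for the Hungarian matcher.
brute_force_accuracy <- function(truth, pred, k) {
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  best <- 0
  for (p in perms(seq_len(k)))
    best <- max(best, mean(p[pred] == truth))
  best
}

# Small everything-usable bin frame over one or more chromosomes.
tiny_bins <- function(n_per_chrom = 10, n_chrom = 1, bin_size = 1000) {
  sizes <- stats::setNames(rep(n_per_chrom * bin_size, n_chrom),
                           paste0("c", seq_len(n_chrom)))
  make_bins(sizes, bin_size)
}
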