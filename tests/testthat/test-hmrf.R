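# small helper: wrap a plain matrix as signal_matrix on a fresh bin frame
as_signals <- function(x) {
  gb <- make_bins(c(chr = nrow(x) * 1000), 1000)
  signal_matrix(gb, x, channels = paste0("ch", seq_len(ncol(x))))
}

test_that("Gaussian log density matches closed forms and a dense-inverse
           oracle", {
  expect_equal(gaussian_log_density(rep(0, 4), rep(0, 4), diag(4)),
               -2 * log(2 * pi), tolerance = 1e-12)
  expect_equal(gaussian_log_density(2, 0, matrix(1)),
               -0.5 * log(2 * pi) - 2, tolerance = 1e-12)
  set.seed(20)
  for (rep in 1:5) {
    d <- sample(2:5, 1)
    a <- matrix(rnorm(d * d), d)
    sigma <- crossprod(a) + diag(d) * 0.1
    mu <- rnorm(d); x <- rnorm(d)
    expect_equal(gaussian_log_density(x, mu, sigma),
                 dense_mvn_logdens(x, mu, sigma), tolerance = 1e-9)
  }
  expect_error(gaussian_log_density(c(0, 0), c(0, 0),
                                    matrix(c(1, 2, 2, 1), 2)),
               "positive-definite")
})

test_that("GMM initialization recovers well-separated planted clusters,
           deterministically", {
  set.seed(21)
  n <- 1200
  lab <- rep(1:2, each = n)
  x <- matrix(rnorm(2 * n * 3, sd = 1), ncol = 3)
  x[lab == 2, ] <- x[lab == 2, ] + 10 / sqrt(3)   # ||delta mu|| = 10 sigma
  sm <- as_signals(x)
  g1 <- gmm_initialize(sm, k = 2, seed = 5)
  g2 <- gmm_initialize(sm, k = 2, seed = 5)
  expect_identical(g1$model$means, g2$model$means)
  expect_identical(g1$labels, g2$labels)
  mm <- match_labels(lab, g1$labels, k = 2)
  expect_equal(mm$accuracy, 1)
  reord <- g1$model$means[order(g1$model$means[, 1]), ]
  expect_lt(max(abs(reord[1, ] - 0)), 0.1)
  expect_lt(max(abs(reord[2, ] - 10 / sqrt(3))), 0.1)
})

test_that("single-component GMM equals sample moments", {
  set.seed(22)
  x <- matrix(rnorm(200), ncol = 2)
  g <- gmm_initialize(as_signals(x), k = 1, seed = 1)
  expect_equal(as.numeric(g$model$means), colMeans(x))
  # ridge only perturbs the diagonal at 1e-6 relative scale
  expect_equal(g$model$covariances[, , 1], cov(x), tolerance = 1e-5)
})

test_that("initial transition reproduces hand-counted co-occurrence
           ratios", {
  gb <- tiny_bins(3)
  g <- build_graph(gb)                       # chain 0-1-2
  t1 <- initial_transition(c(1L, 1L, 2L), g, k = 2)
  raw <- attr(t1, "raw")
  # edges (1,2),(2,3) labeled [a,a,b]: numerator(a,b) = 1 (both
  # orientations), denominator = sum over stored edges of
  # 1(H_i=a) + 1(H_j=b) = 1 + 2 = 3
  expect_equal(raw[1, 2], 1 / 3)
  expect_equal(raw[1, 1], 2 / 3)             # 2 / (2 + 1)

  t2 <- initial_transition(c(1L, 1L, 1L), g, k = 1)
  expect_equal(attr(t2, "raw")[1, 1], 1)     # 2|E| / 2|E|

  t3 <- initial_transition(c(1L, 2L, 1L), g, k = 2)
  raw3 <- attr(t3, "raw")
  expect_equal(diag(raw3), c(0, 0))          # strictly alternating labels

  # stored matrix is symmetric with unit row sums
  expect_equal(t1, t(t1))
  expect_equal(rowSums(t1), c(1, 1), tolerance = 1e-9)
})

test_that("LBP on an isolated node is the softmax of node potential plus
           log mixture", {
  gb <- make_bins(c(chr = 1000), 1000)
  sm <- signal_matrix(gb, matrix(0.3), channels = "ch1")
  g <- build_graph(gb)
  model <- hmrf_model(matrix(c(-1, 1), 2, 1),
                      array(rep(diag(1), 2), c(1, 1, 2)),
                      matrix(0.5, 2, 2), mixture = c(0.7, 0.3))
  bs <- lbp_infer(model, g, sm)
  np <- sapply(1:2, function(h)
    gaussian_log_density(0.3, model$means[h, ], matrix(1))) +
    log(c(0.7, 0.3))
  expect_equal(exp(bs$log_beliefs)[1, ], exp(np) / sum(exp(np)),
               tolerance = 1e-12)
})

test_that("LBP equals exact enumeration on a two-node model and on random
           trees", {
  set.seed(23)
  # 2-node, k = 2 toy with hand-set potentials
  gb <- make_bins(c(chr = 2000), 1000)
  x <- matrix(c(0.2, -0.5), ncol = 1)
  sm <- signal_matrix(gb, x, channels = "ch1")
  g <- build_graph(gb)
  t_mat <- matrix(c(0.8, 0.2, 0.2, 0.8), 2)
  model <- hmrf_model(matrix(c(-1, 1), 2, 1),
                      array(rep(0.5, 2), c(1, 1, 2)),
                      t_mat)
  bs <- lbp_infer(model, g, sm, tol = 0, max_iter = 50,
                  use_mixture_weights = FALSE)
  np <- sapply(1:2, function(h)
    gaussian_log_density(x, model$means[h, , drop = FALSE],
                         matrix(0.5)))
  exact <- enumerate_marginals(np, data.frame(i = 1, j = 2), t_mat)
  expect_equal(exp(bs$log_beliefs), exact, tolerance = 1e-9)

  # random trees, n <= 8, k <= 4: BP is exact on trees
  for (rep in 1:10) {
    n <- sample(3:8, 1); k <- sample(2:4, 1)
    gbt <- make_bins(c(chr = n * 1000), 1000)
    xt <- matrix(rnorm(n * 2), ncol = 2)
    smt <- signal_matrix(gbt, xt, channels = c("a", "b"))
    tree <- random_tree_edges(n)
    # adjacency-free graph: mask nothing, provide the tree as "hic" pairs
    gt <- build_graph(gbt, intra_pairs = data.frame(i = tree$i - 1,
                                                    j = tree$j - 1))
    # keep only tree edges (drop the chain adjacency to get a real tree)
    gt$edges <- gt$edges[grepl("hic", gt$edges$kind), , drop = FALSE]
    w <- matrix(runif(k * k, 0.2, 1), k); w <- (w + t(w)) / 2
    t_k <- w / rowSums(w); t_k <- (t_k + t(t_k)) / 2
    means <- matrix(rnorm(k * 2, sd = 2), k)
    covs <- array(0, c(2, 2, k))
    for (h in 1:k) covs[, , h] <- diag(2) * runif(1, 0.5, 2)
    mk <- hmrf_model(means, covs, t_k)
    bst <- lbp_infer(mk, gt, smt, tol = 0, max_iter = 100,
                     use_mixture_weights = FALSE)
    npt <- sapply(1:k, function(h)
      gaussian_log_density(xt, means[h, ], covs[, , h]))
    exact_t <- enumerate_marginals(npt, tree, t_k)
    expect_equal(exp(bst$log_beliefs), exact_t, tolerance = 1e-8)
  }
})

test_that("messages and beliefs exponentiate to probability simplices", {
  set.seed(24)
  ds <- simulate_dataset(n_bins_total = 120, n_chrom = 2, k = 3, seed = 9)
  g <- build_graph(ds$bins,
                   intra_pairs = data.frame(i = c(0, 5, 10),
                                            j = c(30, 40, 50)))
  gi <- gmm_initialize(ds$signals, 3, seed = 2)
  model <- gi$model
  model$transition <- initial_transition(gi$labels, g, k = 3)
  bs <- lbp_infer(model, g, ds$signals)
  expect_equal(rowSums(exp(bs$log_messages)),
               rep(1, nrow(bs$log_messages)), tolerance = 1e-9)
  expect_equal(rowSums(exp(bs$log_beliefs)),
               rep(1, nrow(bs$log_beliefs)), tolerance = 1e-9)
  expect_true(bs$converged)
})

test_that("E-step posteriors follow the neighbor-product formula", {
  # uniform compatibility: posterior reduces to the emission posterior
  gb <- make_bins(c(chr = 3000), 1000)
  x <- matrix(c(-0.5, 0.1, 0.7), ncol = 1)
  sm <- signal_matrix(gb, x, channels = "ch1")
  g <- build_graph(gb)
  model <- hmrf_model(matrix(c(-1, 1), 2, 1),
                      array(rep(1, 2), c(1, 1, 2)),
                      matrix(0.5, 2, 2))
  post <- estep_posteriors(model, g, sm, hard_states = c(1L, 1L, 2L))
  emis <- sapply(1:2, function(h)
    gaussian_log_density(x, model$means[h, ], matrix(1)))
  expect_equal(post, exp(emis) / rowSums(exp(emis)), tolerance = 1e-12)

  # equal emissions, one neighbor fixed at state 1, t(1,1) = 0.9:
  # posterior of state 1 is exactly 0.9
  gb2 <- make_bins(c(chr = 2000), 1000)
  sm2 <- signal_matrix(gb2, matrix(c(0, 0), ncol = 1), channels = "ch1")
  m2 <- hmrf_model(matrix(c(0, 0), 2, 1),
                   array(rep(1, 2), c(1, 1, 2)),
                   matrix(c(0.9, 0.1, 0.1, 0.9), 2))
  g2 <- build_graph(gb2)
  post2 <- estep_posteriors(m2, g2, sm2, hard_states = c(1L, 1L))
  expect_equal(post2[2, 1], 0.9, tolerance = 1e-12)
  expect_equal(rowSums(post2), c(1, 1), tolerance = 1e-12)
})

test_that("M-step moments match a naive weighted oracle", {
  set.seed(25)
  n <- 60; d <- 3; k <- 2
  x <- matrix(rnorm(n * d), ncol = d)
  sm <- as_signals(x)
  g <- build_graph(sm$bins)
  prev <- hmrf_model(matrix(0, k, d), array(diag(d), c(d, d, k)),
                     matrix(0.5, k, k))

  # hard posteriors: means are per-state sample means exactly
  lab <- rep(1:2, length.out = n)
  qh <- matrix(0, n, k); qh[cbind(1:n, lab)] <- 1
  mh <- mstep_update(qh, sm, g, prev)
  expect_equal(mh$means[1, ], colMeans(x[lab == 1, ]))
  expect_equal(mh$means[2, ], colMeans(x[lab == 2, ]))

  # uniform posteriors: both means equal the global mean
  qu <- matrix(0.5, n, k)
  mu <- mstep_update(qu, sm, g, prev)
  expect_equal(mu$means[1, ], colMeans(x))
  expect_equal(mu$means[2, ], colMeans(x))

  # random posteriors: naive double-loop oracle for means and covariances
  qr <- matrix(runif(n * k), n); qr <- qr / rowSums(qr)
  mr <- mstep_update(qr, sm, g, prev)
  for (h in 1:k) {
    mu_o <- colSums(x * qr[, h]) / sum(qr[, h])
    expect_equal(mr$means[h, ], mu_o, tolerance = 1e-12)
    s_o <- matrix(0, d, d)
    for (i in 1:n)
      s_o <- s_o + qr[i, h] * tcrossprod(x[i, ] - mu_o)
    s_o <- s_o / sum(qr[, h])
    expect_equal(mr$covariances[, , h], s_o + diag(sum(diag(s_o)) / d * 1e-6, d),
                 tolerance = 1e-10)
  }
  expect_equal(mr$mixture, colMeans(qr))
  # transition is symmetric, row-stochastic
  expect_equal(mr$transition, t(mr$transition))
  expect_equal(rowSums(mr$transition), rep(1, k), tolerance = 1e-9)
})

test_that("full fit recovers planted states and is seed-deterministic", {
  ds <- simulate_dataset(n_bins_total = 800, n_chrom = 2, k = 4, seed = 31)
  res <- spin_pipeline(ds$signals, ds$contacts, k = 4, seed = 7)
  mm <- match_labels(ds$labels[res$fit$assignment$nodes + 1],
                     res$fit$assignment$labels)
  expect_gte(mm$accuracy, 0.95)
  # recovered means within 0.2 channel SDs after matching
  for (h in 1:4) {
    err <- sqrt(sum((res$fit$model$means[h, ] -
                       ds$truth$means[mm$map[h], ])^2))
    expect_lt(err, 0.2)
  }
  res2 <- spin_pipeline(ds$signals, ds$contacts, k = 4, seed = 7)
  expect_identical(res$fit$assignment$labels, res2$fit$assignment$labels)
  expect_identical(res$fit$model$means, res2$fit$model$means)
})

test_that("two replicates with independent noise give concordant maps", {
  ds <- simulate_dataset(n_bins_total = 800, n_chrom = 2, k = 4, seed = 41)
  sig2 <- simulate_signals(ds$labels, ds$truth$means, ds$truth$covariances,
                           ds$bins, seed = 999)
  r1 <- spin_pipeline(ds$signals, ds$contacts, k = 4, seed = 3)
  r2 <- spin_pipeline(sig2, ds$contacts, k = 4, seed = 3)
  ari <- mclust::adjustedRandIndex(r1$fit$assignment$labels,
                                   r2$fit$assignment$labels)
  expect_gte(ari, 0.8)
})

test_that("speckle ranking orders states by channel mean and is invariant
           to input permutation", {
  means <- cbind(SON_TSA = c(3, -1, 0.5), other = c(0, 0, 0))
  covs <- array(diag(2), c(2, 2, 3))
  m <- hmrf_model(means, covs, matrix(1 / 3, 3, 3),
                  channels = colnames(means))
  rk <- rank_states(m, "SON_TSA")
  expect_equal(rk, c(3L, 1L, 2L))

  perm <- c(2, 3, 1)
  m2 <- hmrf_model(means[perm, ], covs, matrix(1 / 3, 3, 3),
                   channels = colnames(means))
  rk2 <- rank_states(m2, "SON_TSA")
  # ranked means are identical regardless of input state numbering
  expect_equal(m$means[order(rk), ], m2$means[order(rk2), ])

  set.seed(26)
  means10 <- cbind(SON_TSA = rnorm(10), b = rnorm(10))
  m10 <- hmrf_model(means10, array(diag(2), c(2, 2, 10)),
                    matrix(0.1, 10, 10), channels = colnames(means10))
  rk10 <- rank_states(m10, "SON_TSA")
  expect_equal(order(rk10), order(means10[, 1]))
  expect_error(rank_states(m10, "nope"), "unknown channel")
})

test_that("Hungarian label matching agrees with brute force over
           permutations", {
  set.seed(27)
  for (rep in 1:8) {
    k <- sample(2:5, 1); n <- 40
    truth <- sample.int(k, n, replace = TRUE)
    pred <- truth
    flip <- runif(n) < 0.3
    pred[flip] <- sample.int(k, sum(flip), replace = TRUE)
    pred <- sample.int(k)[pred]          # random relabeling
    mm <- match_labels(truth, pred, k = k)
    expect_equal(mm$accuracy, brute_force_accuracy(truth, pred, k))
  }
})
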