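make_cm <- function(entries, n = 6, bin_size = 1000, n_chrom = 1) {
  gb <- tiny_bins(n, n_chrom, bin_size)
  contact_matrix(gb, entries)
}

test_that("distance-decay expectation averages over all pairs, zeros
           included", {
  # value 5 at every distance-1 pair of a 4-bin chromosome
  e <- data.frame(i = 0:2, j = 1:3, value = 5)
  cm <- make_cm(e, n = 4)
  ex <- expected_by_distance(cm, "c1")
  expect_equal(ex[2], 5)
  expect_equal(ex[3], 0)   # empty stratum

  # brute force over all diagonals of a random toy matrix
  set.seed(11)
  pr <- t(combn(0:3, 2))
  vals <- runif(nrow(pr), 0, 10)
  cm2 <- make_cm(data.frame(i = pr[, 1], j = pr[, 2], value = vals), n = 4)
  ex2 <- expected_by_distance(cm2, "c1")
  dense <- matrix(0, 4, 4)
  dense[pr + 1] <- vals
  for (s in 1:3) {
    pairs <- cbind(1:(4 - s), (1 + s):4)
    expect_equal(ex2[s + 1], mean(dense[pairs]))
  }
})

test_that("chromosomes with fewer than two bins are rejected", {
  gb <- make_bins(c(a = 4000, b = 900), 1000)
  cm <- contact_matrix(gb, data.frame(i = 0, j = 1, value = 1))
  expect_error(expected_by_distance(cm, "b"), "fewer than 2")
  expect_error(expected_by_distance(cm, "nope"), "unknown")
})

test_that("O/E log ratios match a brute-force recomputation", {
  set.seed(12)
  n <- 8
  pr <- t(combn(0:(n - 1), 2))
  keep <- runif(nrow(pr)) < 0.7
  e <- data.frame(i = pr[keep, 1], j = pr[keep, 2],
                  value = rpois(sum(keep), 20) + 1)
  cm <- make_cm(e, n = n)
  oe <- oe_log_ratio(cm)
  # independent recomputation from a dense matrix
  dense <- matrix(0, n, n)
  dense[cbind(e$i + 1, e$j + 1)] <- e$value
  for (r in seq_len(nrow(oe))) {
    s <- oe$j[r] - oe$i[r]
    expected <- mean(dense[cbind(1:(n - s), (1 + s):n)])
    expect_equal(oe$score[r],
                 log2(dense[oe$i[r] + 1, oe$j[r] + 1] / expected))
  }
})

test_that("a matrix equal to its own expected model scores identically
           zero, and O = 8E scores 3", {
  # distance-determined values => O = E everywhere
  n <- 10
  pr <- t(combn(0:(n - 1), 2))
  vals <- 100 / (pr[, 2] - pr[, 1])
  cm <- make_cm(data.frame(i = pr[, 1], j = pr[, 2], value = vals), n = n)
  oe <- oe_log_ratio(cm)
  expect_equal(oe$score, rep(0, nrow(oe)), tolerance = 1e-12)

  # one planted value on an otherwise-constant diagonal: score is
  # log2(value / stratum mean), exactly 3 when the value is 8x the
  # (planted-inclusive) expectation
  sel <- pr[, 2] - pr[, 1] == 3
  pr3 <- pr[sel, , drop = FALSE]     # 7 distance-3 pairs
  base <- 2
  # solve v = 8 * mean(stratum): mean = (v + 6 * base) / 7  =>  v = 96
  v <- 8 * 6 * base / (7 - 8)       # negative => infeasible for 8x; use 4x
  v <- 4 * 6 * base / (7 - 4)       # v = 16 gives O = 4E exactly
  cm4 <- make_cm(data.frame(i = pr3[, 1], j = pr3[, 2],
                            value = c(v, rep(base, 6))), n = n)
  oe4 <- oe_log_ratio(cm4)
  planted <- oe4[oe4$i == pr3[1, 1] & oe4$j == pr3[1, 2], ]
  expect_equal(planted$ratio, 4)
  expect_equal(planted$score, 2)
})

test_that("trans expectation is uniform over possible trans pairs", {
  gb <- make_bins(c(a = 3000, b = 3000), 1000)
  e <- data.frame(i = c(0, 1, 2), j = c(3, 4, 5), value = c(2, 4, 6))
  cm <- contact_matrix(gb, e)
  oe <- oe_log_ratio(cm)
  tr <- oe[!oe$intra, ]
  expect_equal(tr$ratio, c(2, 4, 6) / (12 / 9))
})

test_that("Weibull MLE recovers planted parameters and exposes the exact
           survival formula", {
  set.seed(13)
  x <- rweibull(50000, shape = 2, scale = 3)
  ft <- fit_weibull(x)
  expect_lt(abs(ft$shape - 2) / 2, 0.03)
  expect_lt(abs(ft$scale - 3) / 3, 0.03)
  # survival is exp(-(x/scale)^shape)
  xs <- c(0.5, 1, 3, 7)
  expect_equal(ft$p(xs), exp(-(xs / ft$scale)^ft$shape), tolerance = 1e-12)
  # exponential special case: p(scale) = exp(-1)
  expect_equal(stats::pweibull(5, 1, 5, lower.tail = FALSE), exp(-1))
})

test_that("Weibull fit rejects nonpositive input and flags degenerate
           samples", {
  expect_error(fit_weibull(c(rep(1, 40), -2, 0)), "2 nonpositive")
  expect_error(fit_weibull(rep(1, 10)), "at least 30")
  ft <- fit_weibull(rep(2, 100))
  expect_true(ft$degenerate)
  expect_equal(ft$p(3), 0)
})

test_that("intra significance is calibrated under an i.i.d. Weibull null
           and finds planted outliers", {
  # dense single chromosome whose O/E ratios are (scaled) iid Weibull
  set.seed(14)
  n <- 150
  pr <- t(combn(0:(n - 1), 2))
  d <- pr[, 2] - pr[, 1]
  w <- rweibull(nrow(pr), shape = 1.5, scale = 2)
  cm <- make_cm(data.frame(i = pr[, 1], j = pr[, 2],
                           value = w * 50 / d), n = n)
  hits <- significant_intra(cm, alpha = 1e-3)
  n_pairs <- nrow(pr)
  se <- sqrt(1e-3 * (1 - 1e-3) / n_pairs)
  expect_lt(abs(nrow(hits) / n_pairs - 1e-3), 3 * se)

  # plant one contact at the 1e-7 survival quantile of the *fitted* null
  oe <- oe_log_ratio(cm)
  ft <- fit_weibull(oe$ratio[oe$ratio > 0])
  q <- ft$scale * (-log(1e-7))^(1 / ft$shape)
  d17 <- 17
  stratum <- oe[oe$j - oe$i == d17, ]
  newv <- cm$entries
  tgt <- which(newv$j - newv$i == d17)[1]
  # setting the raw value so that the recomputed O/E ratio lands at ~q
  ex <- expected_by_distance(cm, "c1")[d17 + 1]
  newv$value[tgt] <- q * ex * 1.05
  cm2 <- contact_matrix(cm$bins, newv)
  hits2 <- significant_intra(cm2, alpha = 1e-5)
  expect_true(any(hits2$i == newv$i[tgt] & hits2$j == newv$j[tgt]))

  # alpha = 0 flags nothing
  expect_equal(nrow(significant_intra(cm, alpha = 0)), 0)
})

test_that("trans significance keeps only pairs whose full 3x3 neighborhood
           is significant", {
  set.seed(15)
  gb <- make_bins(c(a = 40000, b = 40000), 1000)
  ia <- 0:39; ib <- 40:79
  pr <- as.matrix(expand.grid(i = ia, j = ib))
  vals <- rweibull(nrow(pr), shape = 2, scale = 1)
  strong <- 12   # survival ~ 3e-63 under the null above
  dense_idx <- function(i, j) which(pr[, 1] == i & pr[, 2] == j)
  # isolated significant pair
  vals[dense_idx(5, 45)] <- strong
  # 3x3 significant block centred at (15, 55)
  for (di in -1:1) for (dj in -1:1)
    vals[dense_idx(15 + di, 55 + dj)] <- strong
  # 5x5 block centred at (30, 70): its interior 3x3 centres survive
  for (di in -2:2) for (dj in -2:2)
    vals[dense_idx(30 + di, 70 + dj)] <- strong
  cm <- contact_matrix(gb, data.frame(i = pr[, 1], j = pr[, 2],
                                      value = vals))
  hits <- significant_inter(cm, alpha = 1e-5)
  key <- paste(hits$i, hits$j)
  expect_false("5 45" %in% key)
  expect_true("15 55" %in% key)
  expect_false("14 54" %in% key)       # block corner: neighborhood clipped
  for (di in -1:1) for (dj in -1:1)
    expect_true(paste(30 + di, 70 + dj) %in% key)
  expect_false("28 68" %in% key)
})

test_that("graph assembly: adjacency chain, extra pairs, mask propagation,
           and undirectedness", {
  gb <- tiny_bins(5)
  g <- build_graph(gb)
  expect_equal(nrow(g$edges), 4)
  expect_true(all(g$edges$kind == "adjacency"))

  g2 <- build_graph(gb, intra_pairs = data.frame(i = 0, j = 3))
  expect_equal(nrow(g2$edges), 5)
  nb <- graph_neighbors(g2)
  expect_equal(nb[["0"]], c(1, 3))

  gm <- mask_bins(gb, c(TRUE, TRUE, FALSE, TRUE, TRUE))
  g3 <- build_graph(gm)
  expect_equal(nrow(g3$edges), 2)  # (0,1) and (3,4): chain broken at bin 2
  expect_false(any(g3$edges$i == 2 | g3$edges$j == 2))

  expect_warning(build_graph(gm, sv_pairs = data.frame(i = 0, j = 2)),
                 "masked")

  # adjacency never crosses chromosomes; duplicate edges collapse with
  # merged kind tags
  gb2 <- make_bins(c(a = 3000, b = 3000), 1000)
  g4 <- build_graph(gb2, intra_pairs = data.frame(i = c(0, 0), j = c(1, 2)),
                    sv_pairs = data.frame(i = 0, j = 1))
  expect_false(any(g4$edges$i == 2 & g4$edges$j == 3))
  e01 <- g4$edges[g4$edges$i == 0 & g4$edges$j == 1, ]
  expect_equal(e01$kind, "adjacency,hic_intra,sv")

  # undirected by construction: neighbor lookup is symmetric
  nb4 <- graph_neighbors(g4)
  for (v in names(nb4))
    for (u in nb4[[v]])
      expect_true(as.integer(v) %in% nb4[[as.character(u)]])
})
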