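#' Default emission means for the synthetic genome
#'
#' State mean vectors over the four emulated channels (SON TSA-seq,
#' Lamin-B1 TSA-seq, Lamin-B1 DamID, nucleolus DamID). Ranked states follow
#' the qualitative lamina-to-speckle gradient: the speckle channel
#' increases with rank while the two lamina channels decrease; the
#' nucleolus channel peaks for mid-rank (interior repressive) states.
#' Alternating offsets on the DamID channels keep the state means spread
#' out in all four dimensions rather than on a single gradient line, so
#' adjacent and non-adjacent states are all mutually well separated
#' (minimum pairwise distance about 4.5 channel standard deviations at the
#' default `separation`).
#'
#' @param k number of states.
#' @param separation half-range of the speckle gradient, in units of the
#'   per-channel standard deviation.
#' @return k x 4 matrix of means with channel column names.
#' @export
default_state_means <- function(k, separation = 4.5) {
  r <- if (k == 1) 0 else seq(-separation, separation, length.out = k)
  alt <- rep_len(c(-1, 1), k)
  alt3 <- rep_len(c(1, -1, 0), k)
  mid <- -abs(r) / 2 + separation / 2
  m <- cbind(SON_TSA = r,
             LaminB1_TSA = -r,
             LaminB1_DamID = -0.8 * r + 2.2 * alt,
             AP3_DamID = 0.3 * mid + 3 * alt3)
  rownames(m) <- NULL
  m
}

#' Simulate a planted state sequence
#'
#' First-order Markov chain per chromosome: stay in the current state with
#' probability `p`, otherwise jump to a uniformly chosen *other* state. The
#' chain restarts (uniform initial state) at each chromosome.
#'
#' @param bins a `genome_bins` frame.
#' @param k number of states.
#' @param persistence stay probability `p` in (0, 1]; the default 0.95
#'   gives mean block lengths of 20 bins (500 kb at 25 kb resolution),
#'   matching the domain-scale block structure of compartmentalization
#'   maps.
#' @param seed integer seed.
#' @return integer vector of states (1..k), one per bin.
#' @export
simulate_states <- function(bins, k, persistence = 0.95, seed = 1) {
  stopifnot(inherits(bins, "genome_bins"), k >= 1,
            persistence > 0, persistence <= 1)
  set.seed(seed)
  cid <- .bin_chrom_id(bins)
  labels <- integer(n_bins(bins))
  for (ci in unique(cid)) {
    idx <- which(cid == ci)
    s <- integer(length(idx))
    s[1] <- sample.int(k, 1)
    if (length(idx) > 1) {
      stay <- stats::runif(length(idx) - 1) < persistence
      for (t in 2:length(idx)) {
        s[t] <- if (stay[t - 1] || k == 1) s[t - 1]
                else sample(setdiff(seq_len(k), s[t - 1]), 1)
      }
    }
    labels[idx] <- s
  }
  labels
}

#' Simulate per-bin observation vectors
#'
#' Draws `O_i ~ N(mu[state_i], Sigma[state_i])` independently per bin, the
#' generative assumption of the HMRF emission model.
#'
#' @param labels integer states per bin.
#' @param means k x d matrix of state means.
#' @param covariances d x d x k array (or a single d x d matrix shared by
#'   all states).
#' @param bins the `genome_bins` frame.
#' @param seed integer seed.
#' @return a `signal_matrix` with channels named after `means` columns.
#' @export
simulate_signals <- function(labels, means, covariances, bins, seed = 1) {
  means <- as.matrix(means)
  k <- nrow(means); d <- ncol(means)
  if (is.matrix(covariances) && length(dim(covariances)) == 2)
    covariances <- array(covariances, dim = c(d, d, k))
  stopifnot(max(labels) <= k, length(labels) == n_bins(bins))
  set.seed(seed)
  chols <- lapply(seq_len(k), function(h) {
    ch <- tryCatch(chol(covariances[, , h]), error = function(e) NULL)
    if (is.null(ch)) stop("state ", h, " covariance is not positive-definite")
    ch
  })
  z <- matrix(stats::rnorm(length(labels) * d), ncol = d)
  x <- matrix(0, length(labels), d)
  for (h in seq_len(k)) {
    sel <- labels == h
    if (!any(sel)) next
    x[sel, ] <- sweep(z[sel, , drop = FALSE] %*% chols[[h]], 2,
                      means[h, ], "+")
  }
  colnames(x) <- colnames(means)
  if (is.null(colnames(x))) colnames(x) <- paste0("channel", seq_len(d))
  signal_matrix(bins, x)
}

#' Simulate a distance-decay contact matrix with state-aware enrichment
#'
#' Intra-chromosomal expected counts fall off as `distance^(-gamma)` and
#' are multiplied by `boost` when the two bins share a planted state;
#' trans pairs get a uniform base rate, boosted the same way. Counts are
#' Poisson-sampled.
#'
#' @param labels integer states per bin.
#' @param bins the `genome_bins` frame.
#' @param decay_exponent distance-decay exponent `gamma` (> 0).
#' @param boost same-state contact multiplier `beta` (>= 1); `beta = 1`
#'   removes the planted structure.
#' @param base_count expected count at bin-distance 1 for unmatched states.
#' @param trans_rate uniform expected count for trans pairs.
#' @param seed integer seed.
#' @return a `contact_matrix` of Poisson counts (zero entries dropped).
#' @export
simulate_contacts <- function(labels, bins, decay_exponent = 1, boost = 4,
                              base_count = 300, trans_rate = 0.05, seed = 1) {
  stopifnot(inherits(bins, "genome_bins"), decay_exponent > 0, boost >= 1,
            length(labels) == n_bins(bins))
  set.seed(seed)
  cid <- .bin_chrom_id(bins)
  idx <- bins$bins$index
  pieces <- list()
  for (ci in unique(cid)) {
    ii <- idx[cid == ci]
    pr <- t(utils::combn(ii, 2))
    d_ <- pr[, 2] - pr[, 1]
    lam <- base_count * d_^(-decay_exponent)
    same <- labels[pr[, 1] + 1L] == labels[pr[, 2] + 1L]
    lam[same] <- lam[same] * boost
    v <- stats::rpois(length(lam), lam)
    keep <- v > 0
    pieces[[length(pieces) + 1L]] <-
      data.frame(i = pr[keep, 1], j = pr[keep, 2], value = v[keep])
  }
  if (length(unique(cid)) > 1) {
    pr <- t(utils::combn(idx, 2))
    trans <- cid[pr[, 1] + 1L] != cid[pr[, 2] + 1L]
    pr <- pr[trans, , drop = FALSE]
    lam <- rep(trans_rate, nrow(pr))
    same <- labels[pr[, 1] + 1L] == labels[pr[, 2] + 1L]
    lam[same] <- lam[same] * boost
    v <- stats::rpois(length(lam), lam)
    keep <- v > 0
    pieces[[length(pieces) + 1L]] <-
      data.frame(i = pr[keep, 1], j = pr[keep, 2], value = v[keep])
  }
  contact_matrix(bins, do.call(rbind, pieces), normalization = "raw")
}

#' Simulate a complete planted-truth dataset
#'
#' End-to-end fixture bundle with the statistical structure the HMRF
#' assumes: a binned genome, a planted Markov state sequence, four
#' correlated Gaussian emission tracks, and a distance-decay contact matrix
#' with within-state enrichment. Defaults describe the reference study
#' conditions used throughout the tests: 2,000 bins over 4 chromosomes,
#' k = 4 states, unit-variance channels with 0.3 correlation, minimum
#' mean separation above 4 channel SDs, and same-state contact boost 4.
#' With `dir` set, everything is also written in the formats the pipeline
#' consumes (bedGraph tracks, triplet contact TSV, chrom.sizes, truth
#' JSON).
#'
#' @param n_bins_total total bins (split evenly over `n_chrom`
#'   chromosomes).
#' @param n_chrom number of chromosomes.
#' @param k number of planted states.
#' @param bin_size bin width in bp.
#' @param persistence Markov stay probability.
#' @param separation speckle-gradient half-range (channel SD units).
#' @param channel_cor common off-diagonal correlation of the emission
#'   covariance.
#' @param decay_exponent,boost,base_count,trans_rate see
#'   [simulate_contacts()].
#' @param means optional k x d mean matrix overriding
#'   [default_state_means()].
#' @param seed integer seed; the whole bundle is bit-reproducible from
#'   (arguments, seed).
#' @param dir optional output directory.
#' @return list with `bins`, `labels`, `signals`, `contacts`, `truth`
#'   (an `hmrf_model` holding the generating parameters), and the `config`.
#' @export
simulate_dataset <- function(n_bins_total = 2000, n_chrom = 4, k = 4,
                             bin_size = 25000, persistence = 0.95,
                             separation = 4.5, channel_cor = 0.3,
                             decay_exponent = 1, boost = 4,
                             base_count = 300, trans_rate = 0.05,
                             means = NULL, seed = 1, dir = NULL) {
  stopifnot(n_bins_total >= n_chrom, n_chrom >= 1, k >= 1,
            channel_cor > -1, channel_cor < 1)
  per_chrom <- rep(floor(n_bins_total / n_chrom), n_chrom)
  per_chrom[1] <- per_chrom[1] + n_bins_total - sum(per_chrom)
  sizes <- stats::setNames(per_chrom * bin_size,
                           paste0("chrS", seq_len(n_chrom)))
  bins <- make_bins(sizes, bin_size)
  if (is.null(means)) means <- default_state_means(k, separation)
  d <- ncol(means)
  sigma <- matrix(channel_cor, d, d); diag(sigma) <- 1
  covs <- array(sigma, dim = c(d, d, k))
  labels <- simulate_states(bins, k, persistence, seed = seed)
  signals <- simulate_signals(labels, means, covs, bins, seed = seed + 1)
  contacts <- simulate_contacts(labels, bins, decay_exponent, boost,
                                base_count, trans_rate, seed = seed + 2)
  truth <- hmrf_model(means, covs,
                      transition = diag(persistence, k) +
                        (1 - persistence) / max(k - 1, 1) *
                        (1 - diag(k)),
                      channels = colnames(means))
  config <- list(n_bins_total = n_bins_total, n_chrom = n_chrom, k = k,
                 bin_size = bin_size, persistence = persistence,
                 separation = separation, channel_cor = channel_cor,
                 decay_exponent = decay_exponent, boost = boost,
                 base_count = base_count, trans_rate = trans_rate,
                 seed = seed)
  out <- list(bins = bins, labels = labels, signals = signals,
              contacts = contacts, truth = truth, config = config)
  if (!is.null(dir)) write_dataset(out, dir)
  out
}
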