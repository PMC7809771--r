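#' Rasterize interval annotations onto bins
#'
#' Assigns each bin the category covering most of it (majority overlap);
#' ties are broken by category name, then first seen. Bins with no overlap
#' get `NA`.
#'
#' @param intervals `data.frame` with `chrom`, `start`, `end` (0-based
#'   half-open) and `name` (category).
#' @param bins a `genome_bins` frame.
#' @return character vector of categories, one per bin.
#' @export
rasterize_annotation <- function(intervals, bins) {
  stopifnot(is.data.frame(intervals),
            all(c("chrom", "start", "end", "name") %in% names(intervals)),
            inherits(bins, "genome_bins"))
  bs <- bins$bin_size
  first_idx <- vapply(bins$chrom_sizes$name, function(cn) {
    w <- which(bins$bins$chrom == cn)[1]
    if (is.na(w)) NA_integer_ else bins$bins$index[w]
  }, 0L)
  cover <- list()
  for (r in seq_len(nrow(intervals))) {
    cn <- intervals$chrom[r]
    if (!cn %in% names(first_idx)) next
    lo <- floor(intervals$start[r] / bs)
    hi <- floor((intervals$end[r] - 1) / bs)
    for (b in lo:hi) {
      gi <- first_idx[[cn]] + b
      ov <- min(intervals$end[r], (b + 1) * bs) -
        max(intervals$start[r], b * bs)
      key <- as.character(gi)
      cover[[key]] <- c(cover[[key]],
                        stats::setNames(ov, intervals$name[r]))
    }
  }
  out <- rep(NA_character_, n_bins(bins))
  for (key in names(cover)) {
    v <- cover[[key]]
    tot <- tapply(v, names(v), sum)
    tot <- tot[order(-tot, names(tot))]
    out[as.integer(key) + 1L] <- names(tot)[1]
  }
  out
}

#' Fold enrichment of annotation categories across states
#'
#' `enrichment(s, c)` is the fraction of state-s bins in category c divided
#' by the genome-wide fraction of bins in category c (observed over
#' expected). An empty state or category yields `NA`.
#'
#' @param states a `state_assignment`, or an integer label vector over the
#'   annotated bins.
#' @param annotation per-bin categories (character/factor; `NA` bins are
#'   dropped), aligned to the assignment's nodes when `states` is a
#'   `state_assignment`.
#' @return an `enrichment_table`: matrix states x categories with
#'   attributes `state_counts` and `category_counts`.
#' @export
fold_enrichment <- function(states, annotation) {
  if (inherits(states, "state_assignment")) {
    labels <- states$labels
    annotation <- annotation[states$nodes + 1L]
  } else {
    labels <- as.integer(states)
  }
  stopifnot(length(labels) == length(annotation))
  keep <- !is.na(annotation) & !is.na(labels)
  labels <- labels[keep]; annotation <- as.character(annotation[keep])
  n <- length(labels)
  cats <- sort(unique(annotation))
  ks <- sort(unique(labels))
  obs <- unclass(table(factor(labels, levels = ks),
                       factor(annotation, levels = cats)))
  state_n <- rowSums(obs)
  cat_n <- colSums(obs)
  enr <- (obs / state_n) / rep(cat_n / n, each = length(ks))
  enr[state_n == 0, ] <- NA_real_
  enr[, cat_n == 0] <- NA_real_
  structure(enr, state_counts = state_n, category_counts = cat_n,
            class = c("enrichment_table", "matrix"))
}

#' Signal profiles around state transition boundaries
#'
#' For each state-transition type (pair of states flanking a boundary
#' between consecutive usable same-chromosome bins), averages a signal
#' track over positions within `flank_bp` of the boundary. Symmetric types
#' are merged: a B->A boundary is mirrored and pooled with A->B, so the
#' first-named state is always on the left. Offsets falling off the
#' chromosome (or on masked bins) are skipped for that boundary only.
#'
#' @param states a `state_assignment`.
#' @param track a `signal_track` on the same bins.
#' @param flank_bp flank size in bp (multiple of the bin size; default
#'   200 kb).
#' @param top_n keep the `top_n` most frequent transition types.
#' @return a `boundary_profiles` object: list of profiles, each with
#'   `type` (`c(left_state, right_state)`), `count`, `offsets` (bp,
#'   position of the bin start relative to the boundary) and `mean`
#'   (average signal per offset).
#' @export
boundary_profile <- function(states, track, flank_bp = 200000L,
                             top_n = 6L) {
  stopifnot(inherits(states, "state_assignment"),
            inherits(track, "signal_track"))
  bins <- states$bins
  if (flank_bp %% bins$bin_size != 0)
    stop("flank_bp must be a multiple of the bin size")
  fl <- flank_bp / bins$bin_size
  nodes <- states$nodes
  cid <- .bin_chrom_id(bins)[nodes + 1L]
  lab <- states$labels
  consec <- which(diff(nodes) == 1L & diff(cid) == 0L &
                    lab[-1] != lab[-length(lab)])
  if (!length(consec))
    return(structure(list(), class = "boundary_profiles"))
  left_state <- lab[consec]; right_state <- lab[consec + 1L]
  # canonical type: smaller state named first; mirrored boundaries flagged
  flip <- left_state > right_state
  type_a <- ifelse(flip, right_state, left_state)
  type_b <- ifelse(flip, left_state, right_state)
  type_key <- paste(type_a, type_b, sep = "->")
  counts <- sort(table(type_key), decreasing = TRUE)
  keep_types <- names(counts)[seq_len(min(top_n, length(counts)))]

  node_value <- rep(NA_real_, n_bins(bins))
  node_value[nodes + 1L] <- track$values[nodes + 1L]
  node_chrom <- .bin_chrom_id(bins)

  profiles <- lapply(keep_types, function(tk) {
    sel <- which(type_key == tk)
    offsets <- c(-fl:-1, 0:(fl - 1))        # bins left / right of boundary
    sums <- numeric(length(offsets)); ns <- integer(length(offsets))
    for (b in sel) {
      lbin <- nodes[consec[b]]              # last bin of the left state
      ch <- node_chrom[lbin + 1L]
      off_here <- if (flip[b]) -1L - offsets else offsets
      pos <- lbin + 1L + off_here           # bin at each (mirrored) offset
      ok <- pos >= 0 & pos < n_bins(bins)
      ok[ok] <- node_chrom[pos[ok] + 1L] == ch &
        !is.na(node_value[pos[ok] + 1L])
      sums[ok] <- sums[ok] + node_value[pos[ok] + 1L]
      ns[ok] <- ns[ok] + 1L
    }
    list(type = as.integer(strsplit(tk, "->")[[1]]),
         count = as.integer(counts[[tk]]),
         offsets = offsets * bins$bin_size,
         mean = ifelse(ns > 0, sums / pmax(ns, 1L), NA_real_),
         n = ns)
  })
  names(profiles) <- keep_types
  structure(profiles, class = "boundary_profiles")
}

#' Predict multi-fraction replication timing from states and histone marks
#'
#' Ensemble-of-trees regression (random forest via \pkg{ranger}) of the
#' 7-fraction Repli-seq percentage vector on the speckle-ranked state
#' (integer 1..k) plus histone modification signal channels, evaluated by
#' leave-one-chromosome-out cross-validation. Bins with a missing value in
#' any input or output are discarded. Defaults follow the standard
#' configuration for this task: 1000 trees, square-root feature sampling,
#' maximum depth 100.
#'
#' @param states a `state_assignment` whose labels are already
#'   speckle-ranked (see [rank_states()]), or an integer vector per bin.
#' @param histone_tracks `signal_matrix` (or plain matrix) of per-bin
#'   covariate channels.
#' @param rt_fractions matrix (bins x 7) of fraction percentages, or a
#'   list of 7 `signal_track`s.
#' @param num_trees,max_depth forest hyperparameters; `mtry` is the square
#'   root of the feature count.
#' @param seed integer seed.
#' @return an `rt_prediction`: `r2` (mean test R^2 across fractions and
#'   folds), `per_chrom` data.frame of per-fold R^2, `importance`
#'   (normalized, summed over fraction models) and `predicted` (bins x 7
#'   matrix of out-of-fold predictions).
#' @export
rt_predict <- function(states, histone_tracks, rt_fractions,
                       num_trees = 1000, max_depth = 100, seed = 1) {
  if (inherits(states, "state_assignment")) {
    bins <- states$bins
    state_vec <- rep(NA_integer_, n_bins(bins))
    state_vec[states$nodes + 1L] <- states$labels
  } else {
    state_vec <- as.integer(states)
    bins <- NULL
  }
  hm <- if (inherits(histone_tracks, "signal_matrix")) {
    if (is.null(bins)) bins <- histone_tracks$bins
    histone_tracks$matrix
  } else as.matrix(histone_tracks)
  rt <- if (is.list(rt_fractions) && !is.data.frame(rt_fractions))
    do.call(cbind, lapply(rt_fractions, .track_values))
  else as.matrix(rt_fractions)
  if (ncol(rt) != 7) stop("expected 7 replication-timing fractions, got ",
                          ncol(rt))
  if (is.null(bins)) stop("cannot determine the bin frame")
  stopifnot(length(state_vec) == n_bins(bins), nrow(hm) == n_bins(bins),
            nrow(rt) == n_bins(bins))
  chrom <- bins$bins$chrom
  feat <- cbind(state = state_vec, hm)
  keep <- stats::complete.cases(feat) & stats::complete.cases(rt)
  feat <- feat[keep, , drop = FALSE]
  rt <- rt[keep, , drop = FALSE]
  chrom <- chrom[keep]
  chroms <- unique(chrom)
  if (length(chroms) < 2)
    stop("leave-one-chromosome-out CV needs at least 2 chromosomes")
  frac_names <- colnames(rt)
  if (is.null(frac_names)) frac_names <- c(paste0("S", 1:6), "G2")
  mtry <- max(1L, floor(sqrt(ncol(feat))))

  imp <- numeric(ncol(feat)); names(imp) <- colnames(feat)
  predicted <- matrix(NA_real_, length(state_vec), 7,
                      dimnames = list(NULL, frac_names))
  per_chrom <- data.frame(chrom = chroms, r2 = NA_real_)
  keep_idx <- which(keep)
  for (ci in seq_along(chroms)) {
    test <- chrom == chroms[ci]
    df_train <- as.data.frame(feat[!test, , drop = FALSE])
    df_test <- as.data.frame(feat[test, , drop = FALSE])
    r2s <- numeric(7)
    for (f in 1:7) {
      df_train$.y <- rt[!test, f]
      rf <- ranger::ranger(dependent.variable.name = ".y",
                           data = df_train,
                           num.trees = num_trees, mtry = mtry,
                           max.depth = max_depth,
                           importance = "impurity",
                           seed = seed + 101 * ci + f,
                           num.threads = 1)
      pred <- stats::predict(rf, data = df_test)$predictions
      r2s[f] <- .r_squared(rt[test, f], pred)
      imp <- imp + rf$variable.importance
      predicted[keep_idx[test], f] <- pred
    }
    per_chrom$r2[ci] <- mean(r2s, na.rm = TRUE)
  }
  structure(list(r2 = mean(per_chrom$r2),
                 per_chrom = per_chrom,
                 importance = imp / sum(imp),
                 predicted = predicted),
            class = "rt_prediction")
}

#' @export
print.rt_prediction <- function(x, ...) {
  cat(sprintf("rt_prediction: mean test R^2 = %.3f over %d chromosomes\n",
              x$r2, nrow(x$per_chrom)))
  cat("top features:\n")
  print(utils::head(sort(x$importance, decreasing = TRUE), 5))
  invisible(x)
}
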