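#' Sparse binned contact matrix
#'
#' Holds upper-triangular sparse entries `(i, j, value)` on the 0-based
#' global bin index of a [make_bins()] frame. Values are contact counts or
#' normalized contact strengths; the `normalization` tag records which.
#'
#' @param bins a `genome_bins` frame.
#' @param entries `data.frame` with columns `i`, `j` (0-based bin indices)
#'   and `value` (non-negative). Entries are canonicalized to `i <= j`;
#'   duplicates are summed.
#' @param normalization tag, e.g. `"raw"` or `"VC_SQRT"`.
#' @return a `contact_matrix` object.
#' @export
contact_matrix <- function(bins, entries, normalization = "raw") {
  stopifnot(inherits(bins, "genome_bins"), is.data.frame(entries))
  stopifnot(all(c("i", "j", "value") %in% names(entries)))
  i <- as.integer(entries$i); j <- as.integer(entries$j)
  v <- as.numeric(entries$value)
  nb <- n_bins(bins)
  if (any(i < 0 | i >= nb | j < 0 | j >= nb))
    stop("contact entry references an invalid bin index")
  if (any(v < 0)) stop("contact values must be non-negative")
  swap <- i > j
  tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp
  key <- paste(i, j)
  if (anyDuplicated(key)) {
    v <- as.numeric(tapply(v, key, sum)[unique(key)])
    keep <- !duplicated(key)
    i <- i[keep]; j <- j[keep]
  }
  o <- order(i, j)
  structure(list(bins = bins,
                 entries = data.frame(i = i[o], j = j[o], value = v[o]),
                 normalization = normalization),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("contact_matrix: %d entries on %d bins (%s)\n",
              nrow(x$entries), n_bins(x$bins), x$normalization))
  invisible(x)
}

#' Square-root vanilla-coverage normalization
#'
#' Fallback normalizer for raw contact matrices: divides each entry by
#' `sqrt(rowsum_i * rowsum_j)`, where row sums are taken over the full
#' symmetric matrix. Entries in zero-coverage rows are dropped.
#'
#' @param cm a `contact_matrix` with raw counts.
#' @return a `contact_matrix` tagged `"VC_SQRT"`.
#' @export
vc_sqrt_normalize <- function(cm) {
  stopifnot(inherits(cm, "contact_matrix"))
  e <- cm$entries
  nb <- n_bins(cm$bins)
  rs <- rep(0, nb)
  add <- rowsum(c(e$value, e$value[e$i != e$j]),
                group = c(e$i, e$j[e$i != e$j]))
  rs[as.integer(rownames(add)) + 1L] <- add[, 1]
  denom <- sqrt(rs[e$i + 1L] * rs[e$j + 1L])
  keep <- denom > 0
  e <- e[keep, , drop = FALSE]
  e$value <- e$value / denom[keep]
  contact_matrix(cm$bins, e, normalization = "VC_SQRT")
}

#' Distance-decay expected contact profile for one chromosome
#'
#' For each bin-distance stratum `s`, the expected value is the mean
#' observed contact over *all* `n - s` pairs at that distance on the
#' chromosome, counting absent sparse entries as observed zeros.
#'
#' @param cm a `contact_matrix`.
#' @param chrom chromosome name.
#' @return numeric vector `expected` where `expected[s + 1]` is the expected
#'   contact at bin-distance `s` (s = 0 .. n-1).
#' @export
expected_by_distance <- function(cm, chrom) {
  stopifnot(inherits(cm, "contact_matrix"))
  gb <- cm$bins
  sel_bins <- gb$bins$chrom == chrom
  if (!any(sel_bins)) stop("unknown chromosome: ", chrom)
  nb <- sum(sel_bins)
  if (nb < 2) stop("chromosome ", chrom, " has fewer than 2 bins")
  idx <- gb$bins$index[sel_bins]
  lo <- min(idx); hi <- max(idx)
  e <- cm$entries
  sel <- e$i >= lo & e$i <= hi & e$j >= lo & e$j <= hi
  s <- e$j[sel] - e$i[sel]
  sums <- rep(0, nb)
  if (any(sel)) {
    add <- rowsum(e$value[sel], group = s)
    sums[as.integer(rownames(add)) + 1L] <- add[, 1]
  }
  npairs <- nb - (0:(nb - 1))
  sums / npairs
}

#' Observed/expected log ratios for all sparse contact entries
#'
#' Intra-chromosomal entries are scored against that chromosome's
#' distance-decay expectation ([expected_by_distance()]); inter-chromosomal
#' entries against a single uniform expectation (total trans signal divided
#' by the number of possible trans pairs). Entries whose expected value is
#' zero are masked (dropped).
#'
#' @param cm a `contact_matrix`.
#' @return `data.frame` with columns `i`, `j`, `value` (observed), `ratio`
#'   (O/E), `score` (log2 O/E) and `intra` (logical).
#' @export
oe_log_ratio <- function(cm) {
  stopifnot(inherits(cm, "contact_matrix"))
  gb <- cm$bins
  cid <- .bin_chrom_id(gb)
  e <- cm$entries
  ci <- cid[e$i + 1L]; cj <- cid[e$j + 1L]
  intra <- ci == cj
  expected <- rep(NA_real_, nrow(e))

  for (k in which(tabulate(cid) >= 2)) {
    chrom <- gb$chrom_sizes$name[k]
    exp_s <- expected_by_distance(cm, chrom)
    sel <- intra & ci == k
    expected[sel] <- exp_s[(e$j[sel] - e$i[sel]) + 1L]
  }
  if (any(!intra)) {
    nb_per <- tabulate(cid)
    n_tot <- sum(nb_per)
    n_trans_pairs <- (n_tot^2 - sum(nb_per^2)) / 2
    expected[!intra] <- sum(e$value[!intra]) / n_trans_pairs
  }
  ratio <- e$value / expected
  keep <- !is.na(expected) & expected > 0
  data.frame(i = e$i[keep], j = e$j[keep], value = e$value[keep],
             ratio = ratio[keep], score = log2(ratio[keep]),
             intra = intra[keep])
}

#' Maximum-likelihood Weibull fit with an upper-tail p-value function
#'
#' Fits a two-parameter Weibull to positive values and returns the
#' parameters together with the survival function
#' `p(x) = exp(-(x / scale)^shape)` used to call significant contacts.
#'
#' @param values positive numeric values (n >= 30).
#' @return list with `shape`, `scale`, `degenerate` flag and `p`, a
#'   vectorized upper-tail p-value function.
#' @export
fit_weibull <- function(values) {
  values <- values[!is.na(values)]
  nbad <- sum(values <= 0)
  if (nbad > 0)
    stop("Weibull fit requires positive values; ", nbad,
         " nonpositive value(s) supplied")
  if (length(values) < 30)
    stop("Weibull fit requires at least 30 values, got ", length(values))
  if (stats::sd(values) / mean(values) < 1e-8) {
    # all values (numerically) identical: shape -> Inf guard
    return(list(shape = Inf, scale = mean(values), degenerate = TRUE,
                p = function(x) as.numeric(x < mean(values))))
  }
  ft <- fitdistrplus::fitdist(values, "weibull")
  shape <- unname(ft$estimate["shape"])
  scale <- unname(ft$estimate["scale"])
  list(shape = shape, scale = scale, degenerate = FALSE,
       p = function(x) stats::pweibull(x, shape = shape, scale = scale,
                                       lower.tail = FALSE))
}

#' Significant intra-chromosomal interactions
#'
#' For each chromosome independently, fits a Weibull null to the positive
#' O/E ratios of the observed contacts and keeps pairs whose upper-tail
#' p-value falls below `alpha` (default 1e-5). A chromosome whose fit fails
#' is skipped with a warning.
#'
#' @param cm a `contact_matrix`.
#' @param alpha significance cutoff on the Weibull survival p-value.
#' @param fit_on `"oe_ratio"` (default) fits the Weibull to positive O/E
#'   ratios; `"contact"` fits it to the normalized contact values instead.
#' @return `data.frame` of significant pairs (`i`, `j`, `p`).
#' @export
significant_intra <- function(cm, alpha = 1e-5,
                              fit_on = c("oe_ratio", "contact")) {
  fit_on <- match.arg(fit_on)
  oe <- oe_log_ratio(cm)
  oe <- oe[oe$intra, , drop = FALSE]
  cid <- .bin_chrom_id(cm$bins)
  out <- list()
  for (k in unique(cid[oe$i + 1L])) {
    sel <- cid[oe$i + 1L] == k
    x <- if (fit_on == "oe_ratio") oe$ratio[sel] else oe$value[sel]
    pos <- x > 0
    ft <- tryCatch(fit_weibull(x[pos]), error = function(e) e)
    if (inherits(ft, "error") || isTRUE(ft$degenerate)) {
      warning("skipping chromosome ", cm$bins$chrom_sizes$name[k],
              ": ", if (inherits(ft, "error")) conditionMessage(ft)
                    else "degenerate Weibull fit")
      next
    }
    p <- rep(1, sum(sel)); p[pos] <- ft$p(x[pos])
    keep <- p < alpha
    out[[length(out) + 1L]] <- data.frame(i = oe$i[sel][keep],
                                          j = oe$j[sel][keep],
                                          p = p[keep])
  }
  if (!length(out)) return(data.frame(i = integer(), j = integer(),
                                      p = numeric()))
  do.call(rbind, out)
}

#' Significant inter-chromosomal interactions with the neighbor rule
#'
#' Calls each trans pair against a Weibull null (one fit per chromosome
#' pair by default), then keeps a pair `(i, j)` only if `(i, j)` itself and
#' all neighboring pairs `(i', j')` with `i' in {i-1, i, i+1}` and
#' `j' in {j-1, j, j+1}` are significant. A missing neighbor (absent entry
#' or chromosome edge) counts as failing, which makes the rule conservative.
#'
#' @param cm a `contact_matrix`.
#' @param alpha significance cutoff.
#' @param pool `"per_pair"` (default) fits one null per chromosome pair;
#'   `"pooled"` fits a single null to all trans contacts.
#' @return `data.frame` of retained pairs (`i`, `j`, `p`).
#' @export
significant_inter <- function(cm, alpha = 1e-5,
                              pool = c("per_pair", "pooled")) {
  pool <- match.arg(pool)
  oe <- oe_log_ratio(cm)
  oe <- oe[!oe$intra, , drop = FALSE]
  if (!nrow(oe)) return(data.frame(i = integer(), j = integer(),
                                   p = numeric()))
  cid <- .bin_chrom_id(cm$bins)
  ci <- cid[oe$i + 1L]; cj <- cid[oe$j + 1L]
  grp <- if (pool == "per_pair") paste(ci, cj) else rep("all", nrow(oe))
  p <- rep(1, nrow(oe))
  for (g in unique(grp)) {
    sel <- grp == g
    pos <- oe$ratio > 0 & sel
    ft <- tryCatch(fit_weibull(oe$ratio[pos]), error = function(e) e)
    if (inherits(ft, "error") || isTRUE(ft$degenerate)) {
      warning("skipping trans group ", g, ": ",
              if (inherits(ft, "error")) conditionMessage(ft)
              else "degenerate Weibull fit")
      next
    }
    p[pos] <- ft$p(oe$ratio[pos])
  }
  sig <- p < alpha
  sig_key <- paste(oe$i[sig], oe$j[sig])
  keep <- logical(nrow(oe))
  cand <- which(sig)
  for (idx in cand) {
    i <- oe$i[idx]; j <- oe$j[idx]
    ok <- TRUE
    for (di in -1:1) {
      for (dj in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii < 0 || jj < 0 || ii >= n_bins(cm$bins) ||
            jj >= n_bins(cm$bins) ||
            cid[ii + 1L] != cid[i + 1L] || cid[jj + 1L] != cid[j + 1L] ||
            !(paste(ii, jj) %in% sig_key)) { ok <- FALSE; break }
      }
      if (!ok) break
    }
    keep[idx] <- ok
  }
  data.frame(i = oe$i[keep], j = oe$j[keep], p = p[keep])
}

#' Build the interaction graph of the hidden Markov random field
#'
#' Nodes are the usable bins; edges are the union of (1) genomic adjacency
#' between consecutive usable bins on the same chromosome, (2) significant
#' intra-chromosomal Hi-C pairs, (3) significant inter-chromosomal Hi-C
#' pairs, and (4) user-supplied structural-variant junction pairs. Duplicate
#' edges are collapsed with merged kind tags; edges touching masked bins are
#' dropped (with a warning for SV pairs).
#'
#' @param bins a `genome_bins` frame (its mask defines the node set).
#' @param intra_pairs,inter_pairs,sv_pairs `data.frame`s with 0-based bin
#'   index columns `i`, `j` (may be `NULL` or empty).
#' @return an `interaction_graph` object.
#' @export
build_graph <- function(bins, intra_pairs = NULL, inter_pairs = NULL,
                        sv_pairs = NULL) {
  stopifnot(inherits(bins, "genome_bins"))
  usable <- which(bins$mask) - 1L          # 0-based usable indices
  cid <- .bin_chrom_id(bins)

  consec <- usable[-length(usable)]
  nxt <- usable[-1]
  adj_ok <- (nxt - consec == 1L) & (cid[consec + 1L] == cid[nxt + 1L])
  edges <- data.frame(i = consec[adj_ok], j = nxt[adj_ok],
                      kind = rep("adjacency", sum(adj_ok)),
                      stringsAsFactors = FALSE)

  add_kind <- function(edges, pairs, kind, warn_masked = FALSE) {
    if (is.null(pairs) || !nrow(pairs)) return(edges)
    i <- as.integer(pairs$i); j <- as.integer(pairs$j)
    swap <- i > j; tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp
    ok <- i != j & bins$mask[i + 1L] & bins$mask[j + 1L]
    if (warn_masked && any(!ok))
      warning(sum(!ok), " ", kind,
              " pair(s) reference a masked bin or self-loop; dropped")
    rbind(edges, data.frame(i = i[ok], j = j[ok],
                            kind = rep(kind, sum(ok)),
                            stringsAsFactors = FALSE))
  }
  edges <- add_kind(edges, intra_pairs, "hic_intra")
  edges <- add_kind(edges, inter_pairs, "hic_inter")
  edges <- add_kind(edges, sv_pairs, "sv", warn_masked = TRUE)

  key <- paste(edges$i, edges$j)
  if (anyDuplicated(key)) {
    kinds <- tapply(edges$kind, key,
                    function(k) paste(sort(unique(k)), collapse = ","))
    keep <- !duplicated(key)
    edges <- edges[keep, , drop = FALSE]
    edges$kind <- as.character(kinds[paste(edges$i, edges$j)])
  }
  edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(bins = bins, nodes = usable, edges = edges),
            class = "interaction_graph")
}

#' @export
print.interaction_graph <- function(x, ...) {
  cat(sprintf("interaction_graph: %d nodes, %d edges (%s)\n",
              length(x$nodes), nrow(x$edges),
              paste(names(table(x$edges$kind)), table(x$edges$kind),
                    sep = ":", collapse = ", ")))
  invisible(x)
}

#' Neighbor sets of an interaction graph
#'
#' @param graph an `interaction_graph`.
#' @return named list mapping each node (0-based bin index, as character) to
#'   the integer vector of its neighbors; nodes without edges map to an
#'   empty vector.
#' @export
graph_neighbors <- function(graph) {
  stopifnot(inherits(graph, "interaction_graph"))
  nb <- split(c(graph$edges$j, graph$edges$i),
              factor(c(graph$edges$i, graph$edges$j), levels = graph$nodes))
  lapply(nb, function(v) sort(unique(v)))
}
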