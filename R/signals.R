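#' Per-bin signal containers
#'
#' A `signal_track` holds one real value per bin of a [make_bins()] frame
#' (`NA` where missing); a `signal_matrix` stacks several channels into the
#' per-bin observation vector used by the HMRF. Rows with a missing value in
#' any channel are masked out: the model requires a complete observation
#' vector per node.
#'
#' @param bins a `genome_bins` frame.
#' @param values numeric vector, one value per bin.
#' @param channel channel label (e.g. `"SON_TSA"`).
#' @param units unit tag, e.g. `"log2_ratio"` or `"percent"`.
#' @return a `signal_track` object.
#' @export
signal_track <- function(bins, values, channel = "signal",
                         units = "log2_ratio") {
  stopifnot(inherits(bins, "genome_bins"))
  values <- as.numeric(values)
  if (length(values) != n_bins(bins))
    stop("value count (", length(values), ") does not equal bin count (",
         n_bins(bins), ")")
  structure(list(bins = bins, values = values, channel = channel,
                 units = units),
            class = "signal_track")
}

#' @rdname signal_track
#' @param tracks a list of `signal_track` objects on the same bin frame, or a
#'   numeric matrix with one column per channel.
#' @param channels channel names when `tracks` is a matrix.
#' @export
signal_matrix <- function(bins, tracks, channels = NULL) {
  stopifnot(inherits(bins, "genome_bins"))
  if (is.matrix(tracks)) {
    m <- tracks
    if (is.null(channels)) channels <- colnames(m)
    if (is.null(channels)) channels <- paste0("channel", seq_len(ncol(m)))
  } else {
    stopifnot(length(tracks) >= 1)
    for (tr in tracks) {
      stopifnot(inherits(tr, "signal_track"))
      if (!.same_bins(tr$bins, bins)) stop("track bin frame mismatch")
    }
    m <- do.call(cbind, lapply(tracks, `[[`, "values"))
    if (is.null(channels)) channels <- vapply(tracks, `[[`, "", "channel")
  }
  if (nrow(m) != n_bins(bins)) stop("matrix rows do not match bin count")
  colnames(m) <- channels
  complete <- stats::complete.cases(m)
  bins <- mask_bins(bins, complete)
  structure(list(bins = bins, channels = channels, matrix = m,
                 mask = bins$mask),
            class = "signal_matrix")
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat(sprintf("signal_matrix: %d bins x %d channels (%s); %d usable\n",
              nrow(x$matrix), length(x$channels),
              paste(x$channels, collapse = ", "), sum(x$mask)))
  invisible(x)
}

# internal: pull a numeric vector out of track-like inputs
.track_values <- function(x) {
  if (inherits(x, "signal_track")) x$values
  else if (is.data.frame(x)) x$value
  else as.numeric(x)
}
.track_replace <- function(x, v) {
  if (inherits(x, "signal_track")) { x$values <- v; x }
  else if (is.data.frame(x)) { x$value <- v; x }
  else v
}

#' Log2 enrichment score between a sample and a control track
#'
#' Computes the depth-normalized log2 ratio used for TSA-seq (pull-down vs
#' input) and DamID (Dam-target vs Dam-only) scores on a common window grid,
#' typically sliding 20 kb windows at 1 kb step:
#' `log2((sample/sample_depth + c) / (control/control_depth + c))`.
#'
#' @param sample_counts,control_counts per-window read counts: numeric
#'   vectors or bedGraph-like `data.frame`s (`chrom,start,end,value`) on an
#'   identical grid.
#' @param sample_depth,control_depth total mapped reads of each library.
#' @param pseudocount pseudocount in read units, added to each count before
#'   depth normalization (so the effective rate offset is
#'   `pseudocount/depth`). With `pseudocount = 0`, windows with zero control
#'   coverage are returned as `NA` (missing).
#' @return the same container type as `sample_counts`, values replaced by
#'   log2 enrichment scores.
#' @export
enrichment_score <- function(sample_counts, control_counts,
                             sample_depth, control_depth,
                             pseudocount = 1) {
  s <- .track_values(sample_counts)
  ctl <- .track_values(control_counts)
  if (length(s) != length(ctl))
    stop("mismatched window grids: ", length(s), " vs ", length(ctl),
         " windows")
  if (is.data.frame(sample_counts) && is.data.frame(control_counts)) {
    if (!identical(sample_counts$chrom, control_counts$chrom) ||
        !isTRUE(all.equal(sample_counts$start, control_counts$start)))
      stop("mismatched window grids: coordinates differ")
  }
  stopifnot(sample_depth > 0, control_depth > 0, pseudocount >= 0)
  if (any(s < 0, na.rm = TRUE) || any(ctl < 0, na.rm = TRUE))
    stop("read counts must be non-negative")
  rs <- s / sample_depth + pseudocount / sample_depth
  rc <- ctl / control_depth + pseudocount / control_depth
  val <- log2(rs / rc)
  val[!is.finite(val)] <- NA_real_
  .track_replace(sample_counts, val)
}

# internal: normalized Hanning window of odd length m (endpoint weights are 0)
.hanning_window <- function(m) {
  n <- seq_len(m) - 1
  w <- 0.5 - 0.5 * cos(2 * pi * n / (m - 1))
  w / sum(w)
}

# internal: same-length weighted moving average with truncated, renormalized
# edges; NA values carry zero weight
.smooth_vec <- function(x, w) {
  n <- length(x)
  half <- (length(w) - 1) / 2
  ok <- !is.na(x)
  xf <- ifelse(ok, x, 0)
  num <- stats::convolve(xf, rev(w), type = "open")
  den <- stats::convolve(as.numeric(ok), rev(w), type = "open")
  num <- num[(half + 1):(half + n)]
  den <- den[(half + 1):(half + n)]
  out <- ifelse(den > 1e-12, num / den, NA_real_)
  out[!ok] <- NA_real_
  out
}

#' Hanning-window smoothing of a fine-grid track
#'
#' Replaces each value by the Hanning-weighted moving average (weights
#' normalized to sum to 1). At chromosome edges the window is truncated and
#' renormalized. Smoothing never crosses a chromosome boundary: when the
#' input is a `data.frame` with a `chrom` column (or a `signal_track`), each
#' chromosome is smoothed independently.
#'
#' @param track numeric vector, bedGraph-like `data.frame`, or
#'   `signal_track` on the fine (e.g. 1 kb step) grid.
#' @param window_length odd window length; 21 is the conventional choice for
#'   TSA-seq/DamID scores.
#' @return same container type as `track`, smoothed.
#' @export
hanning_smooth <- function(track, window_length = 21L) {
  window_length <- as.integer(window_length)
  if (window_length < 3 || window_length %% 2 == 0)
    stop("window_length must be an odd integer >= 3")
  w <- .hanning_window(window_length)
  x <- .track_values(track)
  chrom <- if (is.data.frame(track)) track$chrom
           else if (inherits(track, "signal_track")) track$bins$bins$chrom
           else rep("chr", length(x))
  out <- x
  for (cn in unique(chrom)) {
    sel <- chrom == cn
    out[sel] <- .smooth_vec(x[sel], w)
  }
  .track_replace(track, out)
}

#' Aggregate a fine-grid track into genome bins
#'
#' Each bin takes the arithmetic mean of the fine-grid values whose intervals
#' fall inside it; a bin covered by no (non-missing) fine value becomes `NA`
#' and is masked. The fine grid must nest inside the bins (no fine interval
#' may straddle a bin boundary).
#'
#' @param track bedGraph-like `data.frame` (`chrom,start,end,value`) on the
#'   fine grid.
#' @param bins target `genome_bins` frame.
#' @param channel,units passed to [signal_track()].
#' @return a `signal_track` on `bins`.
#' @export
rebin <- function(track, bins, channel = "signal", units = "log2_ratio") {
  stopifnot(is.data.frame(track), inherits(bins, "genome_bins"))
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(track)))
  bs <- bins$bin_size
  if (!all(track$chrom %in% bins$chrom_sizes$name))
    stop("fine track references unknown chromosome: ",
         paste(setdiff(unique(track$chrom), bins$chrom_sizes$name),
               collapse = ", "))
  bin_lo <- floor(track$start / bs)
  bin_hi <- floor((track$end - 1) / bs)
  if (any(bin_lo != bin_hi))
    stop("grid misalignment: fine intervals straddle bin boundaries (",
         sum(bin_lo != bin_hi), " intervals)")
  # map (chrom, bin-in-chrom) to the global index
  first_idx <- vapply(bins$chrom_sizes$name, function(cn)
    bins$bins$index[match(cn, bins$bins$chrom)], 0L)
  gidx <- first_idx[track$chrom] + bin_lo
  if (any(gidx >= n_bins(bins)))
    stop("fine track extends past chromosome end")
  ok <- !is.na(track$value)
  sums <- rep(0, n_bins(bins)); cnts <- rep(0L, n_bins(bins))
  if (any(ok)) {
    tab <- rowsum(cbind(track$value[ok], 1L), group = gidx[ok])
    at <- as.integer(rownames(tab)) + 1L
    sums[at] <- tab[, 1]; cnts[at] <- tab[, 2]
  }
  vals <- ifelse(cnts > 0, sums / pmax(cnts, 1L), NA_real_)
  bins <- mask_bins(bins, cnts > 0)
  signal_track(bins, vals, channel = channel, units = units)
}

#' Replication-timing fraction percentages
#'
#' Converts seven depth-normalized Repli-seq fraction tracks (S1..S6, G2)
#' into per-bin percentages of the seven-fraction total, after dividing each
#' fraction bin-wise by a G1 control to remove copy-number and mappability
#' bias. Bins with zero (or missing) G1 signal are unmappable and are masked
#' (`NA`) in every output fraction.
#'
#' @param fractions list of exactly 7 tracks (numeric vectors,
#'   `data.frame`s, or `signal_track`s) on a common grid.
#' @param g1_control the G1 control track on the same grid.
#' @return list of 7 tracks of the same container type, values in percent;
#'   at every unmasked bin the seven outputs sum to 100.
#' @export
fraction_percentages <- function(fractions, g1_control) {
  if (length(fractions) != 7)
    stop("exactly 7 fraction tracks required (S1..S6, G2), got ",
         length(fractions))
  g1 <- .track_values(g1_control)
  mat <- vapply(fractions, .track_values, numeric(length(g1)))
  if (nrow(mat) != length(g1)) stop("fraction/control grid mismatch")
  bad <- is.na(g1) | g1 == 0
  norm <- sweep(mat, 1, g1, "/")
  tot <- rowSums(norm)
  pct <- 100 * norm / tot
  pct[bad | !is.finite(tot) | tot == 0, ] <- NA_real_
  lapply(seq_len(7), function(f) {
    out <- .track_replace(fractions[[f]], pct[, f])
    if (inherits(out, "signal_track")) out$units <- "percent"
    out
  })
}
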