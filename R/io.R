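#' Read a UCSC chrom.sizes file
#'
#' @param path two-column TSV (chromosome name, length in bp).
#' @return named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("name", "length"))
  stats::setNames(as.numeric(dt$length), dt$name)
}

#' @rdname read_chrom_sizes
#' @param bins a `genome_bins` frame to write the sizes of.
#' @export
write_chrom_sizes <- function(bins, path) {
  data.table::fwrite(bins$chrom_sizes[, c("name", "length")], path,
                     sep = "\t", col.names = FALSE)
  invisible(path)
}

# internal: read a bedGraph file; returns data.frame(chrom,start,end,value)
.read_bedgraph <- function(path) {
  dt <- tryCatch(
    suppressWarnings(
      data.table::fread(path, header = FALSE, sep = "\t",
                        col.names = c("chrom", "start", "end", "value"))),
    error = function(e) NULL)
  if (is.null(dt) || nrow(dt) == 0 || ncol(dt) < 4)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), value = numeric()))
  as.data.frame(dt)
}

#' Read bedGraph signal tracks onto a bin frame
#'
#' Each bedGraph interval contributes to every bin it overlaps with weight
#' proportional to the overlap; per-bin values are overlap-weighted means.
#' Bins with no coverage are missing, and the resulting `signal_matrix`
#' masks any bin missing in at least one channel. Overlapping intervals
#' within one file are rejected (with the offending line numbers);
#' an empty file yields an all-missing channel with a warning.
#'
#' @param paths character vector of bedGraph paths; names become channel
#'   names (default: file base names without extension).
#' @param bins a `genome_bins` frame.
#' @return a `signal_matrix`.
#' @export
read_tracks <- function(paths, bins) {
  stopifnot(inherits(bins, "genome_bins"), length(paths) >= 1)
  chans <- names(paths)
  if (is.null(chans))
    chans <- sub("\\.(bedgraph|bg|bedGraph|tsv|txt)$", "", basename(paths))
  mats <- lapply(seq_along(paths), function(pi) {
    df <- .read_bedgraph(paths[pi])
    if (nrow(df) == 0) {
      warning("empty track file: ", paths[pi])
      return(rep(NA_real_, n_bins(bins)))
    }
    bad <- setdiff(unique(df$chrom), bins$chrom_sizes$name)
    if (length(bad))
      stop(paths[pi], ": unknown chromosome(s): ",
           paste(bad, collapse = ", "))
    over_end <- df$end > bins$chrom_sizes$length[
      match(df$chrom, bins$chrom_sizes$name)]
    if (any(over_end))
      stop(paths[pi], ": interval(s) beyond chromosome end at line(s) ",
           paste(utils::head(which(over_end), 5), collapse = ", "))
    ord <- order(match(df$chrom, bins$chrom_sizes$name), df$start)
    dfo <- df[ord, ]
    same <- dfo$chrom[-1] == dfo$chrom[-nrow(dfo)]
    olap <- same & (dfo$start[-1] < dfo$end[-nrow(dfo)])
    if (any(olap))
      stop(paths[pi], ": overlapping intervals at line(s) ",
           paste(utils::head(ord[which(olap) + 1L], 5), collapse = ", "))
    .bedgraph_to_bins(df, bins)
  })
  m <- do.call(cbind, mats)
  colnames(m) <- chans
  signal_matrix(bins, m, channels = chans)
}

# internal: overlap-weighted per-bin mean of bedGraph intervals
.bedgraph_to_bins <- function(df, bins) {
  bs <- bins$bin_size
  first_idx <- vapply(bins$chrom_sizes$name, function(cn) {
    bins$bins$index[which(bins$bins$chrom == cn)[1]]
  }, 0L)
  lo <- floor(df$start / bs)
  hi <- floor((df$end - 1) / bs)
  nspan <- hi - lo + 1L
  row_i <- rep(seq_len(nrow(df)), nspan)
  b <- lo[row_i] + (sequence(nspan) - 1L)
  ov <- pmin(df$end[row_i], (b + 1) * bs) - pmax(df$start[row_i], b * bs)
  gi <- first_idx[df$chrom[row_i]] + b
  keep <- !is.na(df$value[row_i])
  num <- rep(0, n_bins(bins)); den <- rep(0, n_bins(bins))
  if (any(keep)) {
    add <- rowsum(cbind(df$value[row_i][keep] * ov[keep], ov[keep]),
                  group = gi[keep])
    at <- as.integer(rownames(add)) + 1L
    num[at] <- add[, 1]; den[at] <- add[, 2]
  }
  ifelse(den > 0, num / den, NA_real_)
}

#' Write a per-bin track as bedGraph
#'
#' @param track a `signal_track` (missing bins are skipped).
#' @param path output path.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "signal_track"))
  b <- track$bins$bins
  keep <- !is.na(track$values)
  data.table::fwrite(data.frame(chrom = b$chrom[keep],
                                start = format(b$start[keep],
                                               scientific = FALSE,
                                               trim = TRUE),
                                end = format(b$end[keep],
                                             scientific = FALSE,
                                             trim = TRUE),
                                value = track$values[keep]),
                     path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a sparse contact matrix
#'
#' Accepts a 3-column triplet TSV (`bin_i`, `bin_j`, `value`, 0-based
#' global bin indices) or a 5-column binned format
#' (`chrom1`, `start1`, `chrom2`, `start2`, `value`).
#'
#' @param path input path.
#' @param bins a `genome_bins` frame.
#' @param normalization tag to record on the matrix.
#' @return a `contact_matrix`.
#' @export
read_contacts <- function(path, bins, normalization = "raw") {
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  if (ncol(dt) == 3) {
    entries <- data.frame(i = dt[[1]], j = dt[[2]], value = dt[[3]])
  } else if (ncol(dt) == 5) {
    first_idx <- vapply(bins$chrom_sizes$name, function(cn) {
      bins$bins$index[which(bins$bins$chrom == cn)[1]]
    }, 0L)
    bad <- setdiff(unique(c(dt[[1]], dt[[3]])), bins$chrom_sizes$name)
    if (length(bad))
      stop(path, ": unknown chromosome(s): ", paste(bad, collapse = ", "))
    entries <- data.frame(
      i = first_idx[dt[[1]]] + floor(dt[[2]] / bins$bin_size),
      j = first_idx[dt[[3]]] + floor(dt[[4]] / bins$bin_size),
      value = dt[[5]])
  } else {
    stop(path, ": expected 3 or 5 columns, got ", ncol(dt))
  }
  contact_matrix(bins, entries, normalization = normalization)
}

#' @rdname read_contacts
#' @param cm a `contact_matrix` to write as triplet TSV.
#' @export
write_contacts <- function(cm, path) {
  data.table::fwrite(cm$entries, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read structural-variant junction pairs
#'
#' Accepts a 2-column TSV of 0-based bin-index pairs, or 6+-column BEDPE
#' (`chrom1,start1,end1,chrom2,start2,end2`): BEDPE anchors are converted
#' to the bin containing the anchor midpoint.
#'
#' @param path input path.
#' @param bins a `genome_bins` frame.
#' @return `data.frame` with columns `i`, `j`.
#' @export
read_sv_pairs <- function(path, bins) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  if (ncol(dt) == 2)
    return(data.frame(i = as.integer(dt[[1]]), j = as.integer(dt[[2]])))
  if (ncol(dt) >= 6) {
    first_idx <- vapply(bins$chrom_sizes$name, function(cn) {
      bins$bins$index[which(bins$bins$chrom == cn)[1]]
    }, 0L)
    mid1 <- (dt[[2]] + dt[[3]]) / 2
    mid2 <- (dt[[5]] + dt[[6]]) / 2
    return(data.frame(
      i = first_idx[dt[[1]]] + floor(mid1 / bins$bin_size),
      j = first_idx[dt[[4]]] + floor(mid2 / bins$bin_size)))
  }
  stop(path, ": expected 2-column pairs or 6-column BEDPE")
}

#' Export an interaction graph as an edge-list TSV
#'
#' @param graph an `interaction_graph`.
#' @param path output path.
#' @export
write_graph <- function(graph, path) {
  data.table::fwrite(graph$edges, path, sep = "\t", col.names = TRUE)
  invisible(path)
}

#' Write a state assignment as BED
#'
#' Adjacent same-state usable bins are merged into intervals; a masked gap
#' or a chromosome change splits an interval. The BED name field carries
#' the state label (`S<label>`), the score field `1000 * mean(max belief)`
#' of the merged bins, clamped to `[0, 1000]`.
#'
#' @param assignment a `state_assignment`.
#' @param path output path.
#' @export
write_states <- function(assignment, path) {
  stopifnot(inherits(assignment, "state_assignment"))
  bins <- assignment$bins
  nodes <- assignment$nodes
  lab <- assignment$labels
  cid <- .bin_chrom_id(bins)[nodes + 1L]
  new_run <- c(TRUE, diff(nodes) != 1L | diff(cid) != 0L |
                 lab[-1] != lab[-length(lab)])
  run_id <- cumsum(new_run)
  b <- bins$bins
  recs <- data.frame(
    chrom = tapply(b$chrom[nodes + 1L], run_id, `[`, 1),
    start = tapply(b$start[nodes + 1L], run_id, min),
    end = tapply(b$end[nodes + 1L], run_id, max),
    name = paste0("S", tapply(lab, run_id, `[`, 1)),
    score = pmin(1000L, pmax(0L, as.integer(round(
      1000 * tapply(assignment$max_belief, run_id, mean)))))
  )
  recs$start <- format(recs$start, scientific = FALSE, trim = TRUE)
  recs$end <- format(recs$end, scientific = FALSE, trim = TRUE)
  data.table::fwrite(recs, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read per-bin state labels from a BED written by [write_states()]
#'
#' @param path BED path.
#' @param bins a `genome_bins` frame.
#' @return integer vector of labels per bin (`NA` where unannotated).
#' @export
read_states <- function(path, bins) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  lab <- rep(NA_integer_, n_bins(bins))
  first_idx <- vapply(bins$chrom_sizes$name, function(cn) {
    bins$bins$index[which(bins$bins$chrom == cn)[1]]
  }, 0L)
  for (r in seq_len(nrow(dt))) {
    lo <- first_idx[dt[[1]][r]] + floor(dt[[2]][r] / bins$bin_size)
    hi <- first_idx[dt[[1]][r]] + floor((dt[[3]][r] - 1) / bins$bin_size)
    lab[(lo:hi) + 1L] <- as.integer(sub("^S", "", dt[[4]][r]))
  }
  lab
}

#' Serialize a fitted model to JSON
#'
#' Single JSON document holding the state means, covariances, compatibility
#' matrix, mixture proportions, channel names, `k`, and an arbitrary
#' configuration echo — enough to reproduce or reload the model exactly.
#'
#' @param model an `hmrf_model`.
#' @param path output path.
#' @param config optional list echoed under `"config"` (seeds, tolerances).
#' @export
write_model_json <- function(model, path, config = NULL) {
  stopifnot(inherits(model, "hmrf_model"))
  obj <- list(k = model$k, d = model$d, channels = model$channels,
              means = model$means,
              covariances = lapply(seq_len(model$k), function(h)
                model$covariances[, , h]),
              transition = model$transition,
              mixture = model$mixture,
              config = config)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  k <- obj$k; d <- obj$d
  covs <- array(0, dim = c(d, d, k))
  for (h in seq_len(k)) {
    ch <- if (is.list(obj$covariances)) obj$covariances[[h]]
          else obj$covariances[h, , ]
    covs[, , h] <- matrix(as.numeric(as.matrix(ch)), d, d)
  }
  m <- hmrf_model(matrix(as.numeric(obj$means), k, d,
                         dimnames = list(NULL, obj$channels)),
                  covs, matrix(as.numeric(obj$transition), k, k),
                  obj$mixture, channels = obj$channels)
  attr(m, "config") <- obj$config
  m
}

#' Write a simulated dataset bundle to disk
#'
#' Emits the exact input formats the pipeline consumes: `chrom.sizes`,
#' one bedGraph per emission channel, a triplet-TSV contact matrix, and a
#' `truth.json` holding the planted labels, the generating model, and the
#' generator configuration (sufficient for permutation-invariant scoring
#' via [match_labels()] without re-running generation).
#'
#' @param dataset result of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_chrom_sizes(dataset$bins, file.path(dir, "chrom.sizes"))
  for (ch in dataset$signals$channels) {
    tr <- signal_track(dataset$bins,
                       dataset$signals$matrix[, ch], channel = ch)
    write_bedgraph(tr, file.path(dir, paste0(ch, ".bedgraph")))
  }
  write_contacts(dataset$contacts, file.path(dir, "contacts.tsv"))
  truth <- list(labels = dataset$labels,
                config = dataset$config,
                means = dataset$truth$means,
                covariances = lapply(seq_len(dataset$truth$k), function(h)
                  dataset$truth$covariances[, , h]),
                transition = dataset$truth$transition,
                channels = dataset$truth$channels)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a dataset bundle written by [write_dataset()]
#'
#' @param dir dataset directory.
#' @return list with `bins`, `signals`, `contacts`, `labels`, `config`.
#' @export
read_dataset <- function(dir) {
  sizes <- read_chrom_sizes(file.path(dir, "chrom.sizes"))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  bins <- make_bins(sizes, truth$config$bin_size)
  paths <- file.path(dir, paste0(truth$channels, ".bedgraph"))
  names(paths) <- truth$channels
  signals <- read_tracks(paths, bins)
  contacts <- read_contacts(file.path(dir, "contacts.tsv"), bins)
  list(bins = bins, signals = signals, contacts = contacts,
       labels = as.integer(truth$labels), config = truth$config)
}
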