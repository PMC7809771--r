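#' Build a binned genome coordinate frame
#'
#' Tiles each chromosome left to right with fixed-width, non-overlapping bins
#' in 0-based half-open (BED) coordinates. The last bin of a chromosome may be
#' shorter than `bin_size`. Bins carry a contiguous 0-based `index` running
#' across chromosomes in the order given, and a per-bin logical `mask` marking
#' bins usable for modelling (all `TRUE` at construction; masked down later as
#' signal channels report missing data).
#'
#' @param chrom_sizes two-column `data.frame` (name, length in bp), or a named
#'   numeric vector of chromosome lengths.
#' @param bin_size bin width in bp. The default, 25 kb, is the working
#'   resolution for compartmentalization states.
#' @return an object of class `genome_bins`.
#' @examples
#' gb <- make_bins(c(chr1 = 100e3, chr2 = 60e3), bin_size = 25e3)
#' n_bins(gb)
#' @export
make_bins <- function(chrom_sizes, bin_size = 25000L) {
  if (is.numeric(chrom_sizes) && !is.null(names(chrom_sizes))) {
    chrom_sizes <- data.frame(name = names(chrom_sizes),
                              length = as.numeric(chrom_sizes))
  }
  stopifnot(is.data.frame(chrom_sizes), ncol(chrom_sizes) >= 2)
  names(chrom_sizes)[1:2] <- c("name", "length")
  chrom_sizes$name <- as.character(chrom_sizes$name)
  chrom_sizes$length <- as.numeric(chrom_sizes$length)
  if (anyDuplicated(chrom_sizes$name))
    stop("duplicate chromosome name: ",
         paste(unique(chrom_sizes$name[duplicated(chrom_sizes$name)]),
               collapse = ", "))
  if (any(!is.finite(chrom_sizes$length)) || any(chrom_sizes$length <= 0))
    stop("chromosome lengths must be positive")
  bin_size <- as.numeric(bin_size)
  if (length(bin_size) != 1 || !is.finite(bin_size) || bin_size <= 0)
    stop("bin_size must be a single positive number")

  per_chrom <- lapply(seq_len(nrow(chrom_sizes)), function(ci) {
    len <- chrom_sizes$length[ci]
    nb <- ceiling(len / bin_size)
    start <- (seq_len(nb) - 1) * bin_size
    data.frame(chrom = chrom_sizes$name[ci],
               start = start,
               end = pmin(start + bin_size, len))
  })
  bins <- do.call(rbind, per_chrom)
  bins$index <- seq_len(nrow(bins)) - 1L   # 0-based global index
  rownames(bins) <- NULL

  structure(list(chrom_sizes = chrom_sizes,
                 bin_size = bin_size,
                 bins = bins,
                 mask = rep(TRUE, nrow(bins))),
            class = "genome_bins")
}

#' Number of bins in a `genome_bins` frame
#' @param x a `genome_bins` object.
#' @return integer bin count.
#' @export
n_bins <- function(x) {
  stopifnot(inherits(x, "genome_bins"))
  nrow(x$bins)
}

#' Update the usability mask of a bin frame
#'
#' @param x a `genome_bins` object.
#' @param mask logical vector, one value per bin; `FALSE` marks a bin
#'   unusable. Combined with the existing mask by logical AND.
#' @return the updated `genome_bins`.
#' @export
mask_bins <- function(x, mask) {
  stopifnot(inherits(x, "genome_bins"), is.logical(mask),
            length(mask) == n_bins(x))
  x$mask <- x$mask & !is.na(mask) & mask
  x
}

#' @export
print.genome_bins <- function(x, ...) {
  cat(sprintf("genome_bins: %d chromosomes, %d bins of %g bp (%d usable)\n",
              nrow(x$chrom_sizes), n_bins(x), x$bin_size, sum(x$mask)))
  invisible(x)
}

# internal: chromosome id (integer) per bin, in chrom_sizes order
.bin_chrom_id <- function(gb) {
  match(gb$bins$chrom, gb$chrom_sizes$name)
}

# internal: check two frames describe the same binning
.same_bins <- function(a, b) {
  identical(a$chrom_sizes$name, b$chrom_sizes$name) &&
    isTRUE(all.equal(a$chrom_sizes$length, b$chrom_sizes$length)) &&
    a$bin_size == b$bin_size
}
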