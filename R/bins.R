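#' Build a fixed-width genome bin frame
#'
#' Divides each chromosome into consecutive fixed-width bins (0-based,
#' half-open), keeping a final partial bin when the chromosome length is not
#' a multiple of the bin size. The flat bin index runs chromosome-major in
#' the order the chromosomes are given, so every track sharing the frame is
#' a plain numeric vector of length `n_bins(bins)`.
#'
#' @param chrom_sizes A two-column data.frame (name, length) as produced by
#'   [read_chrom_sizes()], or a named numeric vector of chromosome lengths.
#' @param bin_size Bin width in bp (default 200, roughly a nucleosome plus
#'   spacer).
#' @return An object of class `genome_bins`.
#' @examples
#' b <- make_bins(c(chr1 = 1000, chr2 = 450), bin_size = 200)
#' n_bins(b)  # 5 + 3, the last chr2 bin covers [400, 450)
#' @export
make_bins <- function(chrom_sizes, bin_size = 200L) {
  if (is.data.frame(chrom_sizes)) {
    chrom <- as.character(chrom_sizes[[1L]])
    len <- as.numeric(chrom_sizes[[2L]])
  } else {
    chrom <- names(chrom_sizes)
    len <- as.numeric(chrom_sizes)
  }
  if (length(chrom) == 0L || is.null(chrom))
    stop("chrom_sizes must name at least one chromosome")
  if (anyDuplicated(chrom))
    stop("duplicate chromosome name: ", chrom[duplicated(chrom)][1L])
  if (any(!is.finite(len)) || any(len < 1))
    stop("all chromosome lengths must be >= 1")
  bin_size <- as.integer(bin_size)
  if (is.na(bin_size) || bin_size < 1L) stop("bin_size must be >= 1")
  nb <- as.integer(ceiling(len / bin_size))
  structure(list(
    chrom = chrom,
    chrom_length = stats::setNames(len, chrom),
    bin_size = bin_size,
    bins_per_chrom = stats::setNames(nb, chrom),
    offset = stats::setNames(c(0L, cumsum(nb)[-length(nb)]), chrom),
    n = sum(nb)
  ), class = "genome_bins")
}

#' Read a UCSC chrom.sizes file
#'
#' @param path Two-column TSV of chromosome name and length in bp.
#' @return A data.frame with columns `chrom` and `length`.
#' @export
read_chrom_sizes <- function(path) {
  cs <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = 1), data.table = FALSE)
  if (ncol(cs) < 2L) stop("chrom.sizes must have two columns: ", path)
  data.frame(chrom = cs[[1L]], length = as.numeric(cs[[2L]]))
}

#' Number of bins in a frame
#' @param bins A `genome_bins` object.
#' @export
n_bins <- function(bins) bins$n

#' Per-bin chromosome names (flat order)
#' @param bins A `genome_bins` object.
#' @export
bin_chroms <- function(bins) rep(bins$chrom, bins$bins_per_chrom)

#' Per-bin start coordinates (0-based, flat order)
#' @param bins A `genome_bins` object.
#' @export
bin_starts <- function(bins) {
  unlist(lapply(bins$bins_per_chrom,
                function(k) seq.int(0L, length.out = k) * bins$bin_size),
         use.names = FALSE)
}

#' Per-bin end coordinates (half-open, truncated at chromosome ends)
#' @param bins A `genome_bins` object.
#' @export
bin_ends <- function(bins) {
  ends <- bin_starts(bins) + bins$bin_size
  pmin(ends, rep(bins$chrom_length, bins$bins_per_chrom))
}

#' @export
print.genome_bins <- function(x, ...) {
  cat("genome_bins:", length(x$chrom), "chromosome(s),",
      x$n, "bins of", x$bin_size, "bp\n")
  invisible(x)
}

same_bins <- function(a, b) {
  identical(a$chrom, b$chrom) &&
    identical(unname(a$chrom_length), unname(b$chrom_length)) &&
    a$bin_size == b$bin_size
}

stop_if_frame_mismatch <- function(a, b) {
  if (!same_bins(a, b)) stop("tracks are defined on different genome bin frames")
}
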