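#' Construct a binned signal track
#'
#' A `binned_track` pairs a `genome_bins` frame with one non-negative value
#' per bin (raw read counts or transformed signal).
#'
#' @param bins A `genome_bins` frame.
#' @param values Numeric vector of length `n_bins(bins)`, all finite and >= 0.
#' @param label Sample label used in outputs and logs.
#' @return An object of class `binned_track` with a cached `total` signal.
#' @export
binned_track <- function(bins, values, label = "track") {
  stopifnot(inherits(bins, "genome_bins"))
  values <- as.numeric(values)
  if (length(values) != bins$n)
    stop("values has length ", length(values), " but the frame has ",
         bins$n, " bins")
  if (any(!is.finite(values))) stop("track values must be finite")
  if (any(values < 0)) stop("track values must be non-negative")
  structure(list(bins = bins, values = values, label = label,
                 total = sum(values)),
            class = "binned_track")
}

#' @export
print.binned_track <- function(x, ...) {
  cat(sprintf("binned_track '%s': %d bins, total signal %.6g, %.1f%% non-zero\n",
              x$label, x$bins$n, x$total, 100 * mean(x$values > 0)))
  invisible(x)
}

#' Read a bedgraph file onto a bin frame
#'
#' Intervals aligned to bin boundaries load exactly; otherwise each bin
#' receives the length-weighted mean of the overlapping interval values
#' (uncovered stretches count as 0, so an interval covering half a bin at
#' value v contributes v/2). Bins with no coverage are 0.
#'
#' @param path Path to a 4-column bedgraph (chrom, start, end, value);
#'   `track`, `browser` and `#` lines are ignored.
#' @param bins A `genome_bins` frame.
#' @param label Sample label; defaults to the file name.
#' @param on_unknown_chrom `"error"` (default) rejects intervals on
#'   chromosomes absent from `bins`; `"skip"` drops them.
#' @param on_overhang `"error"` (default) rejects intervals that extend past
#'   the chromosome end; `"truncate"` clips them.
#' @return A [binned_track()].
#' @export
read_bedgraph <- function(path, bins, label = NULL,
                          on_unknown_chrom = c("error", "skip"),
                          on_overhang = c("error", "truncate")) {
  stopifnot(inherits(bins, "genome_bins"))
  on_unknown_chrom <- match.arg(on_unknown_chrom)
  on_overhang <- match.arg(on_overhang)
  if (is.null(label)) label <- sub("\\.(bedgraph|bdg|bg)$", "", basename(path))

  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  if (length(lineno) == 0L)
    return(binned_track(bins, numeric(bins$n), label))

  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 4L))
    stop("malformed bedgraph line ", lineno[which(nf < 4L)[1L]],
         " in ", path, ": fewer than 4 fields")
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  value <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 4L)))
  bad <- !is.finite(start) | !is.finite(end) | !is.finite(value) | end <= start
  if (any(bad))
    stop("malformed bedgraph line ", lineno[which(bad)[1L]], " in ", path)

  known <- chrom %in% bins$chrom
  if (!all(known)) {
    if (on_unknown_chrom == "error")
      stop("bedgraph line ", lineno[which(!known)[1L]],
           ": unknown chromosome '", chrom[which(!known)[1L]], "'")
    chrom <- chrom[known]; start <- start[known]
    end <- end[known]; value <- value[known]; lineno <- lineno[known]
  }
  if (length(chrom) == 0L)
    return(binned_track(bins, numeric(bins$n), label))

  clen <- bins$chrom_length[chrom]
  over <- end > clen
  if (any(over)) {
    if (on_overhang == "error")
      stop("bedgraph line ", lineno[which(over)[1L]],
           ": interval extends past the end of ", chrom[which(over)[1L]])
    end <- pmin(end, clen)
    ok <- end > start
    chrom <- chrom[ok]; start <- start[ok]; end <- end[ok]; value <- value[ok]
  }

  bs <- bins$bin_size
  b0 <- floor(start / bs)
  b1 <- floor((end - 1) / bs)
  span <- as.integer(b1 - b0 + 1)
  row <- rep.int(seq_along(span), span)
  bin <- b0[row] + sequence(span) - 1
  piece_lo <- pmax(start[row], bin * bs)
  piece_hi <- pmin(end[row], (bin + 1) * bs)
  flat <- bins$offset[chrom[row]] + bin + 1

  contrib <- rowsum(value[row] * (piece_hi - piece_lo), flat)
  vals <- numeric(bins$n)
  vals[as.integer(rownames(contrib))] <- contrib[, 1L]
  width <- bin_ends(bins) - bin_starts(bins)
  binned_track(bins, vals / width, label)
}

#' Write a binned track as bedgraph
#'
#' @param track A [binned_track()].
#' @param path Output path.
#' @param merge_adjacent Collapse runs of equal (printed) values within a
#'   chromosome into single intervals (default TRUE).
#' @param digits Significant digits printed per value (default 6); the
#'   write/read round trip reproduces values to this precision.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, merge_adjacent = TRUE, digits = 6L) {
  stopifnot(inherits(track, "binned_track"))
  bins <- track$bins
  chrom <- bin_chroms(bins)
  start <- bin_starts(bins)
  end <- bin_ends(bins)
  val <- sprintf(paste0("%.", digits, "g"), track$values)
  if (merge_adjacent) {
    new_run <- c(TRUE, val[-1L] != val[-length(val)] |
                   chrom[-1L] != chrom[-length(chrom)])
    first <- which(new_run)
    last <- c(first[-1L] - 1L, length(val))
    lines <- sprintf("%s\t%.0f\t%.0f\t%s",
                     chrom[first], start[first], end[last], val[first])
  } else {
    lines <- sprintf("%s\t%.0f\t%.0f\t%s", chrom, start, end, val)
  }
  writeLines(lines, path)
  invisible(path)
}
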