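#' Per-bin peak/background mask
#'
#' @param bins A `genome_bins` frame.
#' @param is_peak Logical vector, one entry per bin; background is the
#'   complement.
#' @return An object of class `region_mask`.
#' @export
region_mask <- function(bins, is_peak) {
  stopifnot(inherits(bins, "genome_bins"))
  is_peak <- as.logical(is_peak)
  if (length(is_peak) != bins$n || anyNA(is_peak))
    stop("is_peak must be a complete logical vector of length n_bins(bins)")
  structure(list(bins = bins, is_peak = is_peak), class = "region_mask")
}

#' @export
print.region_mask <- function(x, ...) {
  cat(sprintf("region_mask: %d / %d bins are peak\n",
              sum(x$is_peak), x$bins$n))
  invisible(x)
}

#' Call peak bins at a stated FDR
#'
#' Converts a -log10 p-value track back to p-values and applies
#' Benjamini-Hochberg across all bins; bins passing at level `fdr` are
#' peaks. A raw p-value cutoff is available for compatibility runs.
#'
#' @param pvals A [binned_track()] of -log10 p-values.
#' @param fdr Target false discovery rate in (0,1) (default 0.1).
#' @param method `"bh"` (default) or `"raw"` (plain p <= fdr cutoff).
#' @return A [region_mask()].
#' @export
call_regions_fdr <- function(pvals, fdr = 0.1, method = c("bh", "raw")) {
  stopifnot(inherits(pvals, "binned_track"))
  method <- match.arg(method)
  if (!is.finite(fdr) || fdr <= 0 || fdr >= 1) stop("fdr must be in (0,1)")
  if (pvals$bins$n == 0L) stop("empty track")
  p <- 10^(-pvals$values)
  hit <- switch(method,
                bh = stats::p.adjust(p, method = "BH") <= fdr,
                raw = p <= fdr)
  region_mask(pvals$bins, hit)
}

#' Intersect per-dataset masks into common peak / common background regions
#'
#' Common peaks are bins called as peaks in every dataset; common background
#' are bins called as background in every dataset. Both sets must be
#' non-empty for normalization to be fittable.
#'
#' @param masks A list of >= 2 [region_mask()] objects on one frame.
#' @return A `common_regions` list with `common_peak` and
#'   `common_background` masks and `n_datasets`.
#' @export
common_regions <- function(masks) {
  if (length(masks) < 2L) stop("need at least two masks")
  bins <- masks[[1L]]$bins
  for (m in masks) {
    stopifnot(inherits(m, "region_mask"))
    stop_if_frame_mismatch(bins, m$bins)
  }
  peak <- Reduce(`&`, lapply(masks, `[[`, "is_peak"))
  backg <- Reduce(`&`, lapply(masks, function(m) !m$is_peak))
  if (!any(peak) || !any(backg))
    stop("fitting impossible: common ",
         if (!any(peak)) "peak" else "background",
         " regions are empty across the ", length(masks),
         " datasets; consider relaxing the FDR threshold")
  structure(list(common_peak = region_mask(bins, peak),
                 common_background = region_mask(bins, backg),
                 n_datasets = length(masks)),
            class = "common_regions")
}

#' @export
print.common_regions <- function(x, ...) {
  cat(sprintf(
    "common_regions over %d datasets: %d common peak, %d common background bins\n",
    x$n_datasets, sum(x$common_peak$is_peak),
    sum(x$common_background$is_peak)))
  invisible(x)
}

#' Fraction of reads (signal) in peaks
#'
#' The standard FRiP quality score: the share of a track's total signal
#' falling in its peak bins, used here as the signal-to-noise estimate.
#'
#' @param track A [binned_track()] with positive total signal.
#' @param mask The track's own peak [region_mask()].
#' @return A number in `[0, 1]`.
#' @export
frip <- function(track, mask) {
  stopifnot(inherits(track, "binned_track"), inherits(mask, "region_mask"))
  stop_if_frame_mismatch(track$bins, mask$bins)
  if (track$total <= 0) stop("track has zero total signal")
  sum(track$values[mask$is_peak]) / track$total
}

#' Choose or synthesize the reference track for normalization
#'
#' @param tracks List of >= 2 [binned_track()] objects on one frame.
#' @param masks Per-track peak masks (needed for `mode = "max_frip"`).
#' @param mode `"max_frip"` (default; the highest-SNR input wins, ties break
#'   to the first by input order), `"median"`/`"mean"` (a synthesized
#'   per-bin median/mean track), or an integer index / track label.
#' @return A list with the reference `track`, its `index` (NA when
#'   synthesized), the `mode`, and per-track `frip` scores when computed.
#' @export
select_reference <- function(tracks, masks = NULL, mode = "max_frip") {
  if (length(tracks) < 2L) stop("need at least two tracks")
  bins <- tracks[[1L]]$bins
  for (t in tracks) stop_if_frame_mismatch(bins, t$bins)
  frips <- NULL
  if (is.numeric(mode)) {
    i <- as.integer(mode)
    if (i < 1L || i > length(tracks)) stop("reference index out of range")
    return(list(track = tracks[[i]], index = i, mode = "index", frip = NULL))
  }
  labels <- vapply(tracks, `[[`, "", "label")
  if (!mode %in% c("max_frip", "median", "mean")) {
    i <- match(mode, labels)
    if (is.na(i)) stop("no track labelled '", mode, "'")
    return(list(track = tracks[[i]], index = i, mode = "label", frip = NULL))
  }
  if (mode == "max_frip") {
    if (is.null(masks) || length(masks) != length(tracks))
      stop("max_frip reference selection needs one peak mask per track")
    frips <- mapply(frip, tracks, masks)
    i <- which.max(frips)  # ties: first by input order
    return(list(track = tracks[[i]], index = i, mode = mode, frip = frips))
  }
  mat <- vapply(tracks, `[[`, numeric(bins$n), "values")
  vals <- if (mode == "median") apply(mat, 1L, stats::median) else rowMeans(mat)
  list(track = binned_track(bins, vals, paste0("reference.", mode)),
       index = NA_integer_, mode = mode, frip = NULL)
}

#' Export a mask's peak regions as BED3
#'
#' Contiguous peak bins are merged into single intervals.
#'
#' @param mask A [region_mask()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks_bed <- function(mask, path) {
  stopifnot(inherits(mask, "region_mask"))
  bins <- mask$bins
  chrom <- bin_chroms(bins)
  start <- bin_starts(bins)
  end <- bin_ends(bins)
  pk <- mask$is_peak
  if (!any(pk)) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  idx <- which(pk)
  new_run <- c(TRUE, diff(idx) != 1L | chrom[idx[-1L]] != chrom[idx[-length(idx)]])
  first <- idx[new_run]
  last <- idx[c(which(new_run)[-1L] - 1L, length(idx))]
  writeLines(sprintf("%s\t%.0f\t%.0f", chrom[first], start[first], end[last]),
             path)
  invisible(path)
}
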