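# Baseline normalizers for comparison: total-signal scaling, quantile
# matching, and a linear simplification of MA-plot normalization. All three
# are pure functions of their inputs.

#' Total-signal normalization
#'
#' Rescales the target by the ratio of total signals, so the output total
#' equals the reference total exactly. A single scale factor cannot match
#' peak and background regions at the same time when signal-to-noise ratios
#' differ; this is the depth-only baseline.
#'
#' @param reference,target [binned_track()] objects on one frame.
#' @return The rescaled target track.
#' @export
tsnorm <- function(reference, target) {
  stop_if_frame_mismatch(reference$bins, target$bins)
  if (target$total <= 0) stop("target track has zero total signal")
  binned_track(target$bins, target$values * (reference$total / target$total),
               target$label)
}

#' Quantile normalization against a reference track
#'
#' The target value of rank k is replaced by the reference value of rank k,
#' so the output value distribution equals the reference's (exactly so when
#' the target is tie-free). Tied target values receive the mean of the
#' reference values across the tied rank span. Forcing identical
#' distributions equalizes both depth and signal-to-noise, but when the
#' target genuinely has fewer peaks than the reference, background bins are
#' promoted to peak-level values — the classic background-inflation failure
#' mode.
#'
#' @param reference,target [binned_track()] objects on one frame.
#' @return The quantile-matched target track.
#' @export
qtnorm <- function(reference, target) {
  stop_if_frame_mismatch(reference$bins, target$bins)
  out <- numeric(target$bins$n)
  out[order(target$values)] <- sort(reference$values)
  out <- stats::ave(out, target$values, FUN = mean)
  binned_track(target$bins, out, target$label)
}

#' Simplified MA-plot normalization on common peaks
#'
#' On the common peak bins, computes M = log2(ref/tar) and
#' A = (1/2) log2(ref * tar) with a pseudocount, fits the straight line
#' M = b0 + b1 A by least squares, and rescales every bin of the target by
#' 2^(b0 + b1 A_i). This is a deliberate linear simplification of MAnorm's
#' robust curve fit (hence the `manorm-simplified` label in outputs): it
#' reproduces the method's defining behaviour — peak signals are matched,
#' but because the peak-fitted curve is applied genome-wide, background
#' bins are rescaled by it too.
#'
#' @param reference,target [binned_track()] objects on one frame.
#' @param common_peaks A [region_mask()] of common peak bins.
#' @param pseudocount Added to both tracks in the M/A computation
#'   (default 1).
#' @return The rescaled target track, with the fit in
#'   `attr(, "manorm_fit")` (`b0`, `b1`, `method = "manorm-simplified"`).
#' @export
manorm_simplified <- function(reference, target, common_peaks,
                              pseudocount = 1) {
  stop_if_frame_mismatch(reference$bins, target$bins)
  stop_if_frame_mismatch(reference$bins, common_peaks$bins)
  pk <- common_peaks$is_peak
  r <- reference$values[pk] + pseudocount
  t <- target$values[pk] + pseudocount
  if (sum(pk) < 2L) stop("need at least two common-peak bins")
  m <- log2(r / t)
  a <- 0.5 * log2(r * t)
  if (stats::sd(a) < 1e-12) {
    # degenerate MA cloud: fall back to intercept-only (median-M) scaling
    b0 <- stats::median(m)
    b1 <- 0
    message("manorm-simplified: constant A among common peaks; ",
            "falling back to median-M scaling")
  } else {
    fit <- stats::lm.fit(cbind(1, a), m)
    b0 <- fit$coefficients[[1L]]
    b1 <- fit$coefficients[[2L]]
  }
  a_all <- 0.5 * log2((reference$values + pseudocount) *
                        (target$values + pseudocount))
  out <- target$values * 2^(b0 + b1 * a_all)
  res <- binned_track(target$bins, out, target$label)
  attr(res, "manorm_fit") <- list(b0 = b0, b1 = b1,
                                  method = "manorm-simplified")
  res
}
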