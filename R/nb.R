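# Negative-binomial background model for binned read counts.
#
# Convention used throughout: X ~ NB(s, p) with
#   P(X = k) = choose(k + s - 1, k) * p^k * (1 - p)^s,
# so mean = s*p/(1-p), variance = s*p/(1-p)^2, and P(X = 0) = (1-p)^s.
# This is R's pnbinom/rnbinom with prob = 1 - p.

#' Method-of-moments NB estimator
#'
#' Solves `p = (sigma2 - M) / sigma2` and `s = M^2 / (sigma2 - M)` where `M`
#' and `sigma2` are the sample mean and variance of the counts. Requires
#' overdispersion (`sigma2 > M`); at or below the Poisson boundary there is
#' no NB solution.
#'
#' @param values Numeric count vector (ignored when `mean`/`variance` given).
#' @param mean,variance Optional moments supplied directly instead of being
#'   estimated from `values`.
#' @return A list with elements `p` (success probability, in (0,1)) and `s`
#'   (shape, > 0).
#' @examples
#' estimate_nb_moments(mean = 2, variance = 4)  # p = 0.5, s = 2
#' @export
estimate_nb_moments <- function(values = NULL, mean = NULL, variance = NULL) {
  if (is.null(mean) || is.null(variance)) {
    if (is.null(values) || length(values) < 2L)
      stop("need a count vector of length >= 2, or explicit moments")
    mean <- base::mean(values)
    variance <- stats::var(values)
  }
  if (variance <= mean)
    stop("variance (", format(variance), ") <= mean (", format(mean),
         "): counts are not overdispersed; no NB fit ",
         "(a Poisson background may be appropriate)")
  list(p = (variance - mean) / variance, s = mean^2 / (variance - mean))
}

#' Zero-truncated NB estimator (fixed point on the non-zero moments)
#'
#' Binned epigenomic counts are zero-inflated relative to the bulk of the
#' background, so the genome-wide model is estimated from the non-zero bins
#' only. With NM1 and NM2 the mean and mean square of the non-zero counts,
#' the parameters satisfy
#' \deqn{p0 = (1-p)^s, \quad p = 1 - NM1 / (NM2 - NM1^2 (1 - p0)), \quad
#'       s = NM1 (1 - p0)(1 - p) / p,}
#' solved here by fixed-point iteration from `p0 = 0`.
#'
#' @param values Count vector; zeros are dropped internally. Alternatively
#'   pass the moments `nm1`/`nm2` directly.
#' @param nm1,nm2 Optional non-zero mean and non-zero mean of squares.
#' @param tol Convergence tolerance on successive `p0` (default 1e-8).
#' @param max_iter Iteration cap (default 1000).
#' @param p0_init Starting value for the zero probability. Defaults to the
#'   empirical zero fraction of `values`, or to 0 when only moments are
#'   given. For sparse counts the iteration started at 0 can leave the
#'   parameter domain before reaching the root, while the empirical zero
#'   fraction starts it in the root's basin.
#' @return An `nb_background` list: `p`, `s`, `p0`, `model = "nb"`,
#'   `zero_truncated = TRUE`, `iterations`, and `m_ctrl = NA` (set by
#'   [fit_nb_background()]).
#' @examples
#' # non-zero moments of NB(s = 2, p = 0.5): recovers p = 0.5, s = 2, p0 = 0.25
#' estimate_nb_nonzero(nm1 = 8/3, nm2 = 32/3)
#' @export
estimate_nb_nonzero <- function(values = NULL, nm1 = NULL, nm2 = NULL,
                                tol = 1e-8, max_iter = 1000L,
                                p0_init = NULL) {
  if (is.null(nm1) || is.null(nm2)) {
    nz <- values[values > 0]
    if (length(unique(nz)) < 2L)
      stop("need at least two distinct non-zero counts to fit the ",
           "zero-truncated NB model")
    nm1 <- base::mean(nz)
    nm2 <- base::mean(nz^2)
    if (is.null(p0_init)) p0_init <- base::mean(values == 0)
  }
  if (is.null(p0_init)) p0_init <- 0
  p0 <- p0_init
  p <- NA_real_
  s <- NA_real_
  for (it in seq_len(max_iter)) {
    denom <- nm2 - nm1^2 * (1 - p0)
    p_new <- 1 - nm1 / denom
    if (!is.finite(p_new) || p_new <= 0 || p_new >= 1)
      stop("zero-truncated NB fixed point left (0,1) at iteration ", it,
           " (p = ", format(p_new), "); counts may be underdispersed")
    s_new <- nm1 * (1 - p0) * (1 - p_new) / p_new
    p0_new <- (1 - p_new)^s_new
    done <- abs(p0_new - p0) < tol
    p <- p_new; s <- s_new; p0 <- p0_new
    if (done) break
  }
  if (!done)
    stop("zero-truncated NB fixed point did not converge in ", max_iter,
         " iterations (last p = ", format(p), ", p0 = ", format(p0), ")")
  if (p0 > 1 - 1e-3 || s < 1e-6)
    stop("zero-truncated NB fit collapsed to the degenerate all-zero root ",
         "(p0 = ", format(p0), ", s = ", format(s), "): the non-zero ",
         "counts are too heavy-tailed for a single NB component")
  structure(list(p = p, s = s, p0 = p0, model = "nb", m_ctrl = NA_real_,
                 zero_truncated = TRUE, iterations = it),
            class = "nb_background")
}

#' Fit the genome-wide NB background for one IP track
#'
#' Fits the zero-truncated NB model on the background bins of the IP and
#' records `m_ctrl`, the mean control count over the same bins, which scales
#' the per-bin local shape in [nb_pvalue_track()]. With no region mask the
#' whole genome is used; with no control the IP serves as its own control.
#'
#' When fitting genome-wide (no `background` mask yet), strong peak bins can
#' dominate the second moment and push the zero-truncated fit to its
#' degenerate all-zero root; `trim` excludes the top fraction of bins by
#' value before fitting to keep the estimate anchored in the background
#' bulk. Very sparse tracks whose trimmed counts are no longer
#' overdispersed have no NB solution; with `fallback = "poisson"` such
#' tracks get a Poisson background (`model = "poisson"`, rate `lambda`),
#' the mean-equals-variance limit of the NB.
#'
#' @param ip A [binned_track()] of IP counts.
#' @param control Optional control (input) [binned_track()] on the same frame.
#' @param background Which bins to fit on: a logical per-bin vector (TRUE =
#'   use), a [region_mask()] whose member bins are used (e.g. the
#'   `common_background` mask of a [common_regions()] object), or a
#'   `common_regions` object (its common background is used). NULL fits on
#'   all bins.
#' @param trim Fraction of highest-value bins excluded from the fit
#'   (default 0: use all selected bins).
#' @param fallback `"error"` (default) propagates an NB fitting failure;
#'   `"poisson"` substitutes the Poisson background instead.
#' @inheritParams estimate_nb_nonzero
#' @return An `nb_background` with `m_ctrl` set.
#' @export
fit_nb_background <- function(ip, control = NULL, background = NULL,
                              trim = 0, fallback = c("error", "poisson"),
                              tol = 1e-8, max_iter = 1000L) {
  stopifnot(inherits(ip, "binned_track"))
  fallback <- match.arg(fallback)
  if (!is.null(control)) stop_if_frame_mismatch(ip$bins, control$bins)
  sel <- background_selector(background, ip$bins)
  v <- ip$values[sel]
  if (trim > 0) {
    cut <- stats::quantile(v, 1 - trim, names = FALSE)
    keep <- v <= cut
    v <- v[keep]
    sel <- which(sel)[keep]
  }
  bg <- tryCatch(
    estimate_nb_nonzero(v, tol = tol, max_iter = max_iter),
    error = function(e) {
      if (fallback == "error") stop(e)
      structure(list(p = NA_real_, s = NA_real_, p0 = exp(-mean(v)),
                     model = "poisson", lambda = mean(v),
                     m_ctrl = NA_real_, zero_truncated = FALSE,
                     iterations = 0L, note = conditionMessage(e)),
                class = "nb_background")
    })
  ctrl_vals <- if (is.null(control)) ip$values else control$values
  bg$m_ctrl <- mean(ctrl_vals[sel])
  if (!is.finite(bg$m_ctrl) || bg$m_ctrl <= 0)
    stop("mean control signal in the fitting regions must be positive")
  bg
}

background_selector <- function(background, bins) {
  if (is.null(background)) return(rep(TRUE, bins$n))
  if (inherits(background, "common_regions"))
    background <- background$common_background
  if (inherits(background, "region_mask")) {
    stop_if_frame_mismatch(bins, background$bins)
    return(background$is_peak)
  }
  stopifnot(is.logical(background), length(background) == bins$n)
  background
}

#' @export
print.nb_background <- function(x, ...) {
  if (identical(x$model, "poisson"))
    cat(sprintf("nb_background: Poisson fallback, lambda = %.6g\n", x$lambda))
  else
    cat(sprintf(
      "nb_background: p = %.6g, s = %.6g, p0 = %.6g (%s, %d iterations)\n",
      x$p, x$s, x$p0,
      if (isTRUE(x$zero_truncated)) "zero-truncated" else "full moments",
      x$iterations))
  invisible(x)
}

#' Per-bin local expected background from a control track
#'
#' MACS-style local lambda: for each bin the expected background is the
#' maximum of the genome-wide mean and the 1 kb, 5 kb and 10 kb window means
#' centred on the bin (windows truncate at chromosome ends; all in
#' counts-per-bin units). Without a control the windows are computed on the
#' IP itself and the 1 kb window is dropped, so that narrow true signal does
#' not inflate its own background estimate.
#'
#' @param ctrl Control [binned_track()], or the IP track itself when
#'   `has_control = FALSE`.
#' @param has_control Whether `ctrl` is a genuine control.
#' @param windows Window sizes in bp (default 1, 5 and 10 kb).
#' @return A `local_control` list with per-bin `r_ctrl` (always >= the
#'   genome mean), the window set used, and the `has_control` flag.
#' @export
local_control <- function(ctrl, has_control = TRUE,
                          windows = c(1000L, 5000L, 10000L)) {
  stopifnot(inherits(ctrl, "binned_track"))
  if (!has_control) windows <- setdiff(windows, 1000L)
  bins <- ctrl$bins
  r <- rep(mean(ctrl$values), bins$n)
  idx_by_chrom <- split(seq_len(bins$n), rep(seq_along(bins$chrom),
                                             bins$bins_per_chrom))
  for (w in windows) {
    wb <- max(1L, as.integer(round(w / bins$bin_size)))
    for (idx in idx_by_chrom)
      r[idx] <- pmax(r[idx], truncated_roll_mean(ctrl$values[idx], wb))
  }
  structure(list(r_ctrl = r, windows = windows, has_control = has_control,
                 bins = bins),
            class = "local_control")
}

# mean over a w-bin window centred on each position, truncated at the ends
truncated_roll_mean <- function(x, w) {
  n <- length(x)
  left <- (w - 1L) %/% 2L
  right <- w - 1L - left
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - left, 1L)
  hi <- pmin(seq_len(n) + right, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Convert a count track to -log10 p-values under the dynamic NB background
#'
#' Each bin's count is scored against NB(`s_local_i`, `p`) with
#' `s_local_i = s * r_ctrl_i / m_ctrl`: stronger local control signal widens
#' the null and damps the p-value. The upper tail P(X >= x) is evaluated as
#' the regularized incomplete beta `I_p(x, s_local)` — the continuous
#' extension of the NB survival function — so that non-integer normalized
#' signals are scored directly. Zero counts give p-value 1, hence 0 output.
#'
#' @param ip [binned_track()] of (raw or normalized) signal.
#' @param local A [local_control()] on the same frame.
#' @param bg An `nb_background` from [fit_nb_background()] (its `m_ctrl`
#'   must be set).
#' @param cap Cap on the -log10 p-value (default 323, the double underflow
#'   limit); computation is done in log space so the cap, not underflow,
#'   saturates strong signals.
#' @return A [binned_track()] of -log10 p-values.
#' @export
nb_pvalue_track <- function(ip, local, bg, cap = 323) {
  stopifnot(inherits(ip, "binned_track"), inherits(local, "local_control"),
            inherits(bg, "nb_background"))
  stop_if_frame_mismatch(ip$bins, local$bins)
  if (!is.finite(bg$m_ctrl) || bg$m_ctrl <= 0)
    stop("bg$m_ctrl must be positive; fit with fit_nb_background()")
  x <- ip$values
  if (any(!is.finite(x))) stop("non-finite signal values")
  out <- numeric(length(x))
  pos <- x > 0
  if (identical(bg$model, "poisson")) {
    # Poisson limit: P(X >= x) = P(Gamma(x, 1) <= lambda), continuous in x
    lambda <- bg$lambda * local$r_ctrl / bg$m_ctrl
    logp <- stats::pgamma(lambda[pos], x[pos], log.p = TRUE)
  } else {
    s_local <- bg$s * local$r_ctrl / bg$m_ctrl
    logp <- stats::pbeta(bg$p, x[pos], s_local[pos], log.p = TRUE)
  }
  out[pos] <- pmin(-logp / log(10), cap)
  binned_track(ip$bins, out, paste0(ip$label, ".nbp"))
}
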