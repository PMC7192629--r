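# Core two-factor fit. The transform is Y_norm = alpha * Y^beta (equivalently
# log Y_norm = log alpha + beta log Y), with alpha, beta > 0 chosen so that
#   mean(alpha * Y_tar,pk^beta)   = mean(Y_ref,pk)          (common peaks)
#   nzmean(alpha * Y_tar,bg^beta) = nzmean(Y_ref,bg)        (common background)
# The 2x2 system is reduced to one dimension by eliminating alpha:
#   alpha(beta) = mean(Y_ref,pk) / mean(Y_tar,pk^beta)
# and the scalar equation
#   g(beta) = alpha(beta) * nzmean(Y_tar,bg^beta) - nzmean(Y_ref,bg) = 0
# is solved by Newton-Raphson (d/dbeta mean(Y^beta) = mean(Y^beta log Y);
# zeros contribute nothing) with a bracketed-bisection safeguard.

BETA_MIN <- 1e-3
BETA_MAX <- 1e3

#' Fit the two-factor power-law normalization between two tracks
#'
#' Finds `alpha`, `beta` > 0 such that the target's mean signal over the
#' common peak bins and its non-zero mean over the common background bins
#' both match the reference after the transform `alpha * y^beta`. Peak means
#' are taken over all common-peak bins (zeros contribute 0); background
#' means are taken over each track's own non-zero common-background bins,
#' which keeps zero-inflated tracks from dragging the background mean down.
#'
#' @param reference,target [binned_track()] objects on one frame.
#' @param regions A [common_regions()] object (or a list with `common_peak`
#'   and `common_background` masks) on the same frame.
#' @param tol Relative tolerance on the background matching equation
#'   (default 1e-6); the peak equation holds exactly by construction of
#'   `alpha(beta)`.
#' @param max_iter Newton iteration cap (default 100).
#' @return An `s3norm_model`: `alpha`, `beta`, `constraint_residual` (the
#'   larger relative residual of the two matching equations at the
#'   solution), `iterations`, `method` (`"newton"` or `"bisection"`),
#'   labels, and `regions_used` counts.
#' @examples
#' b <- make_bins(c(chr1 = 800), bin_size = 200)
#' cr <- list(common_peak = region_mask(b, c(TRUE, TRUE, FALSE, FALSE)),
#'            common_background = region_mask(b, c(FALSE, FALSE, TRUE, TRUE)))
#' ref <- binned_track(b, c(8, 8, 2, 2), "ref")
#' tar <- binned_track(b, c(4, 4, 2, 2), "tar")
#' fit_s3norm(ref, tar, cr)  # alpha = 0.5, beta = 2
#' @export
fit_s3norm <- function(reference, target, regions, tol = 1e-6,
                       max_iter = 100L) {
  stopifnot(inherits(reference, "binned_track"),
            inherits(target, "binned_track"))
  stop_if_frame_mismatch(reference$bins, target$bins)
  pk <- regions$common_peak$is_peak
  bg <- regions$common_background$is_peak
  stop_if_frame_mismatch(reference$bins, regions$common_peak$bins)
  if (any(pk & bg)) stop("common peak and background regions overlap")

  yrp <- reference$values[pk]
  ytp <- target$values[pk]
  yrb_nz <- reference$values[bg]; yrb_nz <- yrb_nz[yrb_nz > 0]
  ytb_nz <- target$values[bg];    ytb_nz <- ytb_nz[ytb_nz > 0]
  if (length(yrp) == 0L || !any(ytp > 0))
    stop("no common-peak bins with positive target signal")
  if (length(yrb_nz) == 0L || length(ytb_nz) == 0L)
    stop("no non-zero common-background bins in one of the tracks")
  mref_pk <- mean(yrp)
  nzref_bg <- mean(yrb_nz)
  if (mref_pk <= 0) stop("reference common-peak mean must be positive")

  n_pk <- length(ytp)
  ltp <- log(ytp[ytp > 0])
  ltb <- log(ytb_nz)
  n_bg <- length(ltb)
  # All mean(Y^beta) terms are handled in log space (log-mean-exp) so that
  # wide excursions in beta cannot overflow. Zeros contribute 0 to the peak
  # mean (hence the log(n_pk) normalizer over all peak bins) and are absent
  # from the non-zero background mean by construction.
  lme <- function(l, n, beta) {
    m <- max(beta * l)
    w <- exp(beta * l - m)
    sw <- sum(w)
    list(log_mean = m + log(sw) - log(n),      # log mean(Y^beta)
         dlog = sum(w * l) / sw)               # d/dbeta of log mean(Y^beta)
  }
  # g(beta) = mref_pk * nzmean(Ytb^beta) / mean(Ytp^beta) - nzref_bg
  gfun <- function(beta) {
    p <- lme(ltp, n_pk, beta)
    b <- lme(ltb, n_bg, beta)
    val <- exp(log(mref_pk) + b$log_mean - p$log_mean) - nzref_bg
    list(g = val, gprime = (val + nzref_bg) * (b$dlog - p$dlog))
  }
  g <- function(beta) gfun(beta)$g

  gtol <- tol * nzref_bg
  beta <- 1
  method <- "newton"
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    gg <- gfun(beta)
    gb <- gg$g
    if (abs(gb) <= gtol) { converged <- TRUE; break }
    beta_new <- beta - gb / gg$gprime
    if (!is.finite(beta_new) || beta_new <= BETA_MIN || beta_new >= BETA_MAX)
      break
    if (abs(beta_new - beta) < 1e-14 * max(1, abs(beta))) {
      beta <- beta_new
      converged <- abs(g(beta)) <= gtol
      break
    }
    beta <- beta_new
  }
  if (!converged) {
    method <- "bisection"
    bis <- bisect_root(g, gtol)
    beta <- bis$beta
    it <- it + bis$iterations
  }

  log_mpk <- lme(ltp, n_pk, beta)$log_mean
  alpha <- exp(log(mref_pk) - log_mpk)
  res_bg <- abs(exp(log(alpha) + lme(ltb, n_bg, beta)$log_mean) - nzref_bg) /
    nzref_bg
  res_pk <- abs(exp(log(alpha) + log_mpk) - mref_pk) / mref_pk
  structure(list(alpha = alpha, beta = beta,
                 constraint_residual = max(res_pk, res_bg),
                 iterations = it, method = method,
                 target_label = target$label,
                 reference_label = reference$label,
                 regions_used = c(n_common_peak = n_pk,
                                  n_background_nonzero = n_bg)),
            class = "s3norm_model")
}

# Bracketed bisection fallback: scan log-spaced beta for a sign change of g,
# then bisect. Multiple sign changes would contradict the model's uniqueness
# premise and are reported as an error rather than resolved silently.
bisect_root <- function(g, gtol, max_iter = 200L) {
  grid <- exp(seq(log(BETA_MIN), log(BETA_MAX), length.out = 121L))
  gv <- vapply(grid, g, 0)
  flips <- which(sign(gv[-1L]) * sign(gv[-length(gv)]) < 0)
  exact <- which(gv == 0)
  if (length(exact) > 0)
    return(list(beta = grid[exact[1L]], iterations = 0L))
  if (length(flips) == 0L)
    stop("no solution: the background matching equation has no sign change ",
         "for beta in [", BETA_MIN, ", ", BETA_MAX, "]; g at endpoints = ",
         format(gv[1L]), ", ", format(gv[length(gv)]))
  if (length(flips) > 1L)
    stop("multiple candidate roots for beta detected (at grid intervals ",
         paste(signif(grid[flips], 4), collapse = ", "),
         "); the fit is not unique on these regions")
  lo <- grid[flips]; hi <- grid[flips + 1L]
  glo <- gv[flips]
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    gm <- g(mid)
    if (abs(gm) <= gtol || (hi - lo) < 1e-12 * mid)
      return(list(beta = mid, iterations = it))
    if (sign(gm) == sign(glo)) { lo <- mid; glo <- gm } else hi <- mid
  }
  stop("bisection failed to reach tolerance in ", max_iter, " iterations")
}

#' @export
print.s3norm_model <- function(x, ...) {
  cat(sprintf(
    "s3norm_model '%s' -> '%s': alpha = %.6g, beta = %.6g (%s, %d iter, residual %.3g)\n",
    x$target_label, x$reference_label, x$alpha, x$beta, x$method,
    x$iterations, x$constraint_residual))
  invisible(x)
}

#' Apply a fitted power-law normalization to a track
#'
#' Value-wise `alpha * y^beta` with zeros mapped to zeros; strictly
#' increasing on positive values, so ranks are preserved.
#'
#' @param target A [binned_track()].
#' @param model An `s3norm_model` (or any list with finite positive
#'   `alpha` and `beta`).
#' @return A [binned_track()] of normalized signal.
#' @export
apply_s3norm <- function(target, model) {
  stopifnot(inherits(target, "binned_track"))
  if (!is.finite(model$alpha) || !is.finite(model$beta) ||
      model$alpha <= 0 || model$beta <= 0)
    stop("model parameters must be finite and positive")
  out <- numeric(target$bins$n)
  pos <- target$values > 0
  out[pos] <- model$alpha * target$values[pos]^model$beta
  binned_track(target$bins, out, target$label)
}

#' Normalize a set of tracks to a common reference
#'
#' End-to-end orchestration for two or more samples sharing a bin frame.
#' The background model and the training regions are bootstrapped in two
#' passes, because the NB background is defined on the common background
#' regions, which in turn come from p-value tracks:
#'
#' 1. Per sample, a provisional NB background is fitted genome-wide on the
#'    non-zero counts with the top `trim` fraction of bins excluded (so
#'    strong peaks cannot dominate the moments), provisional -log10
#'    p-value tracks are computed, and provisional masks are called at
#'    `fdr`; their intersection gives provisional common regions.
#' 2. Per sample, the zero-truncated NB background is refitted (untrimmed)
#'    on the provisional common background bins, the definitive p-value
#'    tracks and masks are recomputed, and the common regions are
#'    re-intersected.
#'
#' A reference is then selected and each non-reference track is fitted and
#' transformed. Peak masks for training are always called on the raw-count
#' p-value tracks, since the normalization parameters cannot depend on
#' their own output.
#'
#' @param tracks List of >= 2 raw-count [binned_track()] objects.
#' @param controls Optional list of control tracks (NULL entries allowed;
#'   samples without a control use themselves, with the 1 kb local window
#'   dropped).
#' @param fdr FDR threshold defining peak/background bins (default 0.1).
#' @param reference Reference selection mode for [select_reference()]
#'   (default `"max_frip"`).
#' @param signal Which signal to fit and transform: `"counts"` (default;
#'   raw counts are normalized, p-value tracks can then be regenerated from
#'   the normalized counts) or `"pvalue"` (the -log10 p-value tracks
#'   themselves are normalized).
#' @param trim Top fraction of bins excluded from the provisional pass-1
#'   background fit (default 0.01).
#' @param tol,max_iter Passed to [fit_s3norm()].
#' @param cap Passed to [nb_pvalue_track()].
#' @return A list: `normalized` (tracks, input order; the reference is
#'   returned unchanged), `models` (one `s3norm_model` per track; the
#'   reference's is the identity), `pvalue_tracks`, `masks`, `regions`,
#'   `nb_fits`, `local_controls`, `frip`, and `reference` (the
#'   [select_reference()] result).
#' @export
normalize_set <- function(tracks, controls = NULL, fdr = 0.1,
                          reference = "max_frip",
                          signal = c("counts", "pvalue"), trim = 0.01,
                          tol = 1e-6, max_iter = 100L, cap = 323) {
  signal <- match.arg(signal)
  if (length(tracks) < 2L) stop("need at least two tracks to normalize")
  bins <- tracks[[1L]]$bins
  for (t in tracks) stop_if_frame_mismatch(bins, t$bins)
  if (!is.null(controls) && length(controls) != length(tracks))
    stop("controls must be NULL or one (possibly NULL) entry per track")

  labels <- vapply(tracks, `[[`, "", "label")
  n_tr <- length(tracks)
  locs <- vector("list", n_tr)
  pv <- vector("list", n_tr)
  masks <- vector("list", n_tr)
  nb_fits <- vector("list", n_tr)

  stage <- function(expr, lab, what)
    tryCatch(expr, error = function(e)
      stop("sample '", lab, "', stage ", what, ": ",
           conditionMessage(e), call. = FALSE))

  # pass 1: provisional genome-wide (trimmed) background -> provisional regions
  for (i in seq_len(n_tr)) {
    ctrl <- if (!is.null(controls)) controls[[i]] else NULL
    locs[[i]] <- stage(local_control(if (is.null(ctrl)) tracks[[i]] else ctrl,
                                     has_control = !is.null(ctrl)),
                       labels[i], "local control")
    bg0 <- stage(fit_nb_background(tracks[[i]], control = ctrl, trim = trim,
                                   fallback = "poisson"),
                 labels[i], "provisional background fit")
    pv0 <- stage(nb_pvalue_track(tracks[[i]], locs[[i]], bg0, cap = cap),
                 labels[i], "provisional p-value track")
    masks[[i]] <- stage(call_regions_fdr(pv0, fdr = fdr),
                        labels[i], "provisional region call")
  }
  regions0 <- common_regions(masks)

  # pass 2: refit on common background bins -> definitive tracks and regions
  for (i in seq_len(n_tr)) {
    ctrl <- if (!is.null(controls)) controls[[i]] else NULL
    nb_fits[[i]] <- stage(
      fit_nb_background(tracks[[i]], control = ctrl,
                        background = regions0$common_background,
                        trim = trim, fallback = "poisson"),
      labels[i], "background fit")
    pv[[i]] <- stage(nb_pvalue_track(tracks[[i]], locs[[i]], nb_fits[[i]],
                                     cap = cap),
                     labels[i], "p-value track")
    masks[[i]] <- stage(call_regions_fdr(pv[[i]], fdr = fdr),
                        labels[i], "region call")
  }
  regions <- common_regions(masks)
  frips <- mapply(frip, tracks, masks)

  base_tracks <- if (signal == "counts") tracks else pv
  ref <- select_reference(base_tracks, masks, mode = reference)

  models <- vector("list", length(tracks))
  normalized <- vector("list", length(tracks))
  for (i in seq_along(tracks)) {
    if (!is.na(ref$index) && i == ref$index) {
      models[[i]] <- structure(list(
        alpha = 1, beta = 1, constraint_residual = 0, iterations = 0L,
        method = "reference", target_label = labels[i],
        reference_label = labels[i],
        regions_used = c(n_common_peak = sum(regions$common_peak$is_peak),
                         n_background_nonzero = NA_real_)),
        class = "s3norm_model")
      normalized[[i]] <- base_tracks[[i]]
    } else {
      models[[i]] <- fit_s3norm(ref$track, base_tracks[[i]], regions,
                                tol = tol, max_iter = max_iter)
      normalized[[i]] <- apply_s3norm(base_tracks[[i]], models[[i]])
    }
  }
  names(normalized) <- names(models) <- names(pv) <- names(masks) <-
    names(nb_fits) <- names(locs) <- labels
  list(normalized = normalized, models = models, pvalue_tracks = pv,
       masks = masks, regions = regions, nb_fits = nb_fits,
       local_controls = locs,
       frip = stats::setNames(frips, labels), reference = ref)
}
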