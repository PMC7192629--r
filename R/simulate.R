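# Synthetic multi-sample binned tracks with controlled depth, SNR and peak
# sharing, plus exact ground-truth constructions for the power-law fit.
# All randomness is locally seeded: the caller's RNG state is untouched.

with_local_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("a single numeric seed is required")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Configuration for the multi-sample track simulator
#'
#' Defaults describe a deliberately heterogeneous three-sample experiment of
#' the kind the normalization is built for: a common bin frame (2
#' chromosomes x 5 Mb at 200-bp bins, 50,000 bins), a sparse shared
#' negative-binomial background NB(s = 1, p = 0.25) (mean 1/3 counts per
#' bin, ~75% zero bins at unit depth, as 200-bp binned ChIP/ATAC counts
#' are), per-sample depth factors spanning ~7x (echoing real mapped-read
#' totals that range over an order of magnitude), and per-sample peak
#' enrichments of 60/40/20x over background so the FRiP scores differ
#' materially. Half the peaks are shared by all samples (with a further 2x
#' strength boost, as constitutive peaks are the strongest in real data);
#' the rest are sample-specific; peak bins are ~1.5% of the genome.
#'
#' @param n_samples Number of samples (default 3).
#' @param n_chroms,chrom_length,bin_size Bin frame geometry.
#' @param n_peaks Peaks per sample (default 150).
#' @param shared_frac Fraction of each sample's peaks drawn from a common
#'   core present in every sample (default 0.5).
#' @param peak_width_bins Peak width in bins (default 5, i.e. 1 kb).
#' @param nb_s,nb_p Background NB shape and success probability.
#' @param enrichment Per-sample multiplier on the background mean inside
#'   peaks (recycled to `n_samples`).
#' @param shared_boost Extra enrichment multiplier for the peaks shared by
#'   all samples (default 2): constitutively active regions -- promoters of
#'   housekeeping genes and the like -- are typically the strongest peaks
#'   in real data, and it is exactly these common peaks the normalization
#'   trains on.
#' @param depth Per-sample sequencing-depth factor (recycled).
#' @param seed Mandatory integer seed; [simulate_tracks()] is deterministic
#'   given the config.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_samples = 3L, n_chroms = 2L, chrom_length = 5e6,
                       bin_size = 200L, n_peaks = 150L, shared_frac = 0.5,
                       peak_width_bins = 5L, nb_s = 1, nb_p = 0.25,
                       enrichment = c(60, 40, 20), shared_boost = 2,
                       depth = c(1, 0.5, 2), seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples),
              n_chroms = as.integer(n_chroms),
              chrom_length = as.numeric(chrom_length),
              bin_size = as.integer(bin_size),
              n_peaks = as.integer(n_peaks),
              shared_frac = shared_frac,
              peak_width_bins = as.integer(peak_width_bins),
              nb_s = nb_s, nb_p = nb_p,
              enrichment = rep_len(as.numeric(enrichment), n_samples),
              shared_boost = as.numeric(shared_boost),
              depth = rep_len(as.numeric(depth), n_samples),
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_samples >= 1L, n_chroms >= 1L, chrom_length >= bin_size,
              bin_size >= 1L, n_peaks >= 1L, peak_width_bins >= 1L,
              nb_s > 0, nb_p > 0, nb_p < 1, shared_boost > 0,
              all(enrichment > 0), all(depth > 0))
    if (shared_frac < 0 || shared_frac > 1)
      stop("shared_frac must be in [0,1]")
    if (is.na(seed)) stop("seed is mandatory")
  })
  structure(cfg, class = "sim_config")
}

#' Simulate multi-sample binned count tracks with known peak structure
#'
#' Peaks occupy non-overlapping slots of `peak_width_bins` bins: a common
#' core shared by every sample plus sample-specific peaks. Background bins
#' are drawn NB(`nb_s`, `nb_p`) with the mean scaled by the sample's depth
#' factor; peak bins use the same NB shape with the mean further multiplied
#' by the sample's enrichment. Controls (when requested) are peak-free
#' draws from the background model at the matching depth.
#'
#' @param config A [sim_config()].
#' @param make_controls Also simulate a peak-free control per sample.
#' @return A list: `tracks`, `true_masks` (the generating [region_mask()]s,
#'   ground truth for FRiP and region calling), `controls` (or NULL),
#'   `bins`, and `config`.
#' @export
simulate_tracks <- function(config, make_controls = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  sizes <- stats::setNames(rep(cfg$chrom_length, cfg$n_chroms),
                           paste0("chr", seq_len(cfg$n_chroms)))
  bins <- make_bins(sizes, cfg$bin_size)
  n <- bins$n
  n_slots <- n %/% cfg$peak_width_bins
  n_shared <- round(cfg$shared_frac * cfg$n_peaks)
  n_specific <- cfg$n_peaks - n_shared
  need <- n_shared + cfg$n_samples * n_specific
  if (need > n_slots)
    stop("peaks exceed genome capacity: need ", need, " slots of ",
         cfg$peak_width_bins, " bins but only ", n_slots, " exist")

  mu_bg <- cfg$nb_s * cfg$nb_p / (1 - cfg$nb_p)
  with_local_seed(cfg$seed, {
    slots <- sample.int(n_slots, need)
    slot_bins <- function(sl)
      as.vector(outer(seq_len(cfg$peak_width_bins) - 1L,
                      (sl - 1L) * cfg$peak_width_bins + 1L, `+`))
    shared_idx <- if (n_shared > 0) slot_bins(slots[seq_len(n_shared)])
                  else integer(0)
    tracks <- vector("list", cfg$n_samples)
    masks <- vector("list", cfg$n_samples)
    controls <- if (make_controls) vector("list", cfg$n_samples) else NULL
    for (j in seq_len(cfg$n_samples)) {
      own <- if (n_specific > 0)
        slot_bins(slots[n_shared + (j - 1L) * n_specific + seq_len(n_specific)])
      else integer(0)
      is_peak <- logical(n)
      is_peak[c(shared_idx, own)] <- TRUE
      mu <- rep(mu_bg * cfg$depth[j], n)
      mu[is_peak] <- mu[is_peak] * cfg$enrichment[j]
      mu[shared_idx] <- mu_bg * cfg$depth[j] * cfg$enrichment[j] * cfg$shared_boost
      vals <- stats::rnbinom(n, size = cfg$nb_s, mu = mu)
      lab <- paste0("sample", j)
      tracks[[j]] <- binned_track(bins, vals, lab)
      masks[[j]] <- region_mask(bins, is_peak)
      if (make_controls)
        controls[[j]] <- binned_track(
          bins, stats::rnbinom(n, size = cfg$nb_s, mu = mu_bg * cfg$depth[j]),
          paste0(lab, ".ctrl"))
    }
    list(tracks = tracks, true_masks = masks, controls = controls,
         bins = bins, config = cfg)
  })
}

#' Construct a target whose exact fit back to the reference is known
#'
#' Inverts the power-law transform: `target = (ref / alpha)^(1/beta)`
#' value-wise (zeros stay zero), so that refitting the target against the
#' reference recovers (`alpha`, `beta`) exactly in the noise-free case.
#' With `noise = "poisson"` each value is replaced by a Poisson draw with
#' that mean, giving a realistic resampled target whose refit recovers the
#' truth up to sampling error.
#'
#' @param reference A [binned_track()].
#' @param alpha,beta Positive ground-truth parameters.
#' @param noise `"none"` (default) or `"poisson"`.
#' @param seed Required when `noise = "poisson"`.
#' @return A [binned_track()] labelled with the ground truth.
#' @export
construct_transformed_target <- function(reference, alpha, beta,
                                         noise = c("none", "poisson"),
                                         seed = NULL) {
  stopifnot(inherits(reference, "binned_track"))
  noise <- match.arg(noise)
  if (!is.finite(alpha) || !is.finite(beta) || alpha <= 0 || beta <= 0)
    stop("alpha and beta must be finite and positive")
  vals <- numeric(reference$bins$n)
  pos <- reference$values > 0
  vals[pos] <- (reference$values[pos] / alpha)^(1 / beta)
  if (noise == "poisson") {
    if (is.null(seed)) stop("seed is required for poisson noise")
    vals <- with_local_seed(seed, stats::rpois(length(vals), vals))
  }
  binned_track(reference$bins, vals,
               sprintf("%s.inv(a=%g,b=%g)", reference$label, alpha, beta))
}
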