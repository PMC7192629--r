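# Shared fixtures and independent oracles used across the suite.

# a tiny frame: one chromosome, n bins of 200 bp
tiny_bins <- function(n, bin_size = 200L, chrom = "chr1") {
  sizes <- stats::setNames(n * bin_size, chrom)
  make_bins(sizes, bin_size)
}

tiny_track <- function(values, label = "t", bin_size = 200L) {
  binned_track(tiny_bins(length(values), bin_size), values, label)
}

# common regions built directly from boolean vectors (bypasses calling)
regions_from_logical <- function(bins, peak, background = !peak) {
  list(common_peak = region_mask(bins, peak),
       common_background = region_mask(bins, background))
}

# Brute-force BH oracle: tries every observed p-value as the threshold and
# takes the largest one t = p_(k) with p_(k) <= fdr * k / n; rejects all
# p <= t. Independent of stats::p.adjust.
bh_oracle <- function(p, fdr) {
  n <- length(p)
  ps <- sort(p)
  k <- which(ps <= fdr * seq_len(n) / n)
  if (length(k) == 0L) return(rep(FALSE, n))
  p <= ps[max(k)]
}

# Dense grid-search oracle for the S3norm beta: evaluates the background
# matching equation g(beta) on an explicit grid and returns the beta with
# the smallest |g|. Vectorized over the grid via the distinct positive
# values of each side; independent of the package's Newton solver.
grid_fit_oracle <- function(reference, target, regions,
                            grid = seq(0.1, 5, by = 1e-4)) {
  pk <- regions$common_peak$is_peak
  bg <- regions$common_background$is_peak
  yrp <- reference$values[pk]
  ytp <- target$values[pk]
  yrb <- reference$values[bg]; yrb <- yrb[yrb > 0]
  ytb <- target$values[bg];    ytb <- ytb[ytb > 0]
  mref_pk <- mean(yrp)
  nzref_bg <- mean(yrb)
  pm <- function(v, n_tot, gr) {
    # t(weights) %*% exp(outer(log(u), gr)): mean of v^beta over the grid
    u <- table(v[v > 0])
    lu <- log(as.numeric(names(u)))
    w <- as.numeric(u)
    as.numeric(crossprod(w, exp(outer(lu, gr)))) / n_tot
  }
  best_beta <- NA_real_
  best_abs <- Inf
  for (chunk in split(grid, ceiling(seq_along(grid) / 4096))) {
    gvals <- mref_pk * pm(ytb, length(ytb), chunk) /
      pm(ytp, length(ytp), chunk) - nzref_bg
    i <- which.min(abs(gvals))
    if (abs(gvals[i]) < best_abs) {
      best_abs <- abs(gvals[i])
      best_beta <- chunk[i]
    }
  }
  best_beta
}
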