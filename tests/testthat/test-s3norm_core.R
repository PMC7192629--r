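test_that("two-level tracks reproduce the closed-form solution", {
  # ref: peaks 8, background 2; target: peaks 4, background 2
  # dividing the constraints: (4/2)^beta = 8/2 => beta = 2; alpha = 8/16 = 0.5
  b <- tiny_bins(8)
  reg <- regions_from_logical(b, c(rep(TRUE, 4), rep(FALSE, 4)))
  ref <- binned_track(b, c(8, 8, 8, 8, 2, 2, 2, 2), "ref")
  tar <- binned_track(b, c(4, 4, 4, 4, 2, 2, 2, 2), "tar")
  m <- fit_s3norm(ref, tar, reg)
  expect_equal(m$alpha, 0.5, tolerance = 1e-6)
  expect_equal(m$beta, 2, tolerance = 1e-6)
  expect_lt(m$constraint_residual, 1e-6)

  # identity: fitting a track against itself gives (1, 1)
  mi <- fit_s3norm(ref, ref, reg)
  expect_equal(mi$alpha, 1, tolerance = 1e-6)
  expect_equal(mi$beta, 1, tolerance = 1e-6)

  # pure depth difference collapses to a scale factor: (alpha, beta) = (2, 1)
  half <- binned_track(b, ref$values / 2, "half")
  mh <- fit_s3norm(ref, half, reg)
  expect_equal(mh$alpha, 2, tolerance = 1e-6)
  expect_equal(mh$beta, 1, tolerance = 1e-6)
})

test_that("fit rejects degenerate region configurations", {
  b <- tiny_bins(4)
  reg <- regions_from_logical(b, c(TRUE, TRUE, FALSE, FALSE))
  ref <- binned_track(b, c(4, 4, 1, 1), "ref")
  zero_pk <- binned_track(b, c(0, 0, 1, 1), "z")
  expect_error(fit_s3norm(ref, zero_pk, reg), "positive target")
  zero_bg <- binned_track(b, c(4, 4, 0, 0), "z2")
  expect_error(fit_s3norm(ref, zero_bg, reg), "non-zero common-background")
  overlap <- list(common_peak = region_mask(b, c(TRUE, TRUE, TRUE, FALSE)),
                  common_background = region_mask(b, c(FALSE, TRUE, FALSE, TRUE)))
  expect_error(fit_s3norm(ref, ref, overlap), "overlap")
})

test_that("apply_s3norm is the power transform with zeros fixed", {
  tr <- tiny_track(c(0, 4, 1, 9))
  out <- apply_s3norm(tr, list(alpha = 0.5, beta = 2))
  expect_equal(out$values, c(0, 8, 0.5, 40.5))
  expect_equal(apply_s3norm(tr, list(alpha = 1, beta = 1))$values, tr$values)
  expect_error(apply_s3norm(tr, list(alpha = -1, beta = 2)), "positive")
  expect_error(apply_s3norm(tr, list(alpha = 1, beta = NaN)), "positive")
})

test_that("every fitted transform preserves ranks and zeros", {
  withr::local_seed(31)
  sim <- simulate_tracks(sim_config(seed = 41))
  res <- normalize_set(sim$tracks)
  for (i in seq_along(res$normalized)) {
    m <- res$models[[i]]
    expect_gt(m$beta, 0)
    raw <- sim$tracks[[i]]$values
    out <- res$normalized[[i]]$values
    expect_true(all(out[raw == 0] == 0))
    o <- order(raw)
    pos <- raw[o] > 0
    # strictly increasing on strictly increasing positive raw values
    inc <- diff(raw[o][pos]) > 0
    expect_true(all(diff(out[o][pos])[inc] > 0))
  }
})

test_that("noise-free constructed targets are recovered to solver precision", {
  withr::local_seed(37)
  sim <- simulate_tracks(sim_config(n_samples = 1, enrichment = 60, seed = 43))
  ref <- sim$tracks[[1]]
  reg <- regions_from_logical(sim$bins, sim$true_masks[[1]]$is_peak)
  for (i in 1:10) {
    a <- exp(runif(1, log(0.1), log(10)))
    bb <- exp(runif(1, log(0.3), log(3)))
    tar <- construct_transformed_target(ref, a, bb)
    m <- fit_s3norm(ref, tar, reg)
    expect_equal(m$alpha, a, tolerance = 1e-3)
    expect_equal(m$beta, bb, tolerance = 1e-3)
    expect_lt(m$constraint_residual, 1e-6)
  }
})

test_that("Newton solution matches the dense grid-search oracle", {
  withr::local_seed(47)
  sim <- simulate_tracks(sim_config(n_samples = 1, n_chroms = 1,
                                    chrom_length = 4e5, n_peaks = 30,
                                    enrichment = 60, seed = 53))
  ref <- sim$tracks[[1]]
  reg <- regions_from_logical(sim$bins, sim$true_masks[[1]]$is_peak)
  for (i in 1:10) {
    a <- exp(runif(1, log(0.5), log(2)))
    bb <- runif(1, 0.4, 2.5)
    tar <- construct_transformed_target(ref, a, bb, noise = "poisson",
                                        seed = 600 + i)
    m <- fit_s3norm(ref, tar, reg)
    bgrid <- grid_fit_oracle(ref, tar, reg)
    expect_lt(abs(m$beta - bgrid), 1e-4 + 1e-12)
  }
})

test_that("normalize_set returns identical tracks and identity models for duplicates", {
  sim <- simulate_tracks(sim_config(n_samples = 1, seed = 59))
  t1 <- sim$tracks[[1]]
  t2 <- binned_track(sim$bins, t1$values, "copy")
  res <- normalize_set(list(t1, t2))
  expect_equal(res$reference$index, 1L)  # FRiP tie: first wins
  for (m in res$models) {
    expect_equal(m$alpha, 1, tolerance = 1e-6)
    expect_equal(m$beta, 1, tolerance = 1e-6)
  }
  expect_equal(res$normalized[[2]]$values, t1$values, tolerance = 1e-9)
})

test_that("normalize_set equalizes common-region means across a trio", {
  sim <- simulate_tracks(sim_config(seed = 61))
  res <- normalize_set(sim$tracks)
  pk <- res$regions$common_peak$is_peak
  bg <- res$regions$common_background$is_peak
  ref_vals <- res$reference$track$values
  target_pk <- mean(ref_vals[pk])
  rb <- ref_vals[bg]
  target_bg <- mean(rb[rb > 0])
  for (i in seq_along(res$normalized)) {
    v <- res$normalized[[i]]$values
    expect_equal(mean(v[pk]), target_pk, tolerance = 1e-6)
    vb <- v[bg]
    expect_equal(mean(vb[vb > 0]), target_bg, tolerance = 1e-6)
    expect_lt(res$models[[i]]$constraint_residual, 1e-6)
  }
  # FRiP of the simulated samples is ordered by their enrichment
  expect_equal(unname(which.max(res$frip)), 1L)
})

test_that("stage failures carry the sample label and stage name", {
  sim <- simulate_tracks(sim_config(n_samples = 2, seed = 67))
  bad <- binned_track(sim$bins, rep(0, n_bins(sim$bins)), "empty")
  expect_error(normalize_set(list(sim$tracks[[1]], bad)),
               "sample 'empty', stage")
})
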