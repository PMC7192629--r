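test_that("moment estimator inverts the NB mean/variance relations", {
  # mean 2, variance 4: p = (4-2)/4 = 0.5, s = 4/(4-2) = 2, exactly
  est <- estimate_nb_moments(mean = 2, variance = 4)
  expect_identical(est$p, 0.5)
  expect_identical(est$s, 2)

  # self-consistency on analytic moments of any NB(s, p)
  for (par in list(c(3, 0.4), c(0.5, 0.8), c(10, 0.1))) {
    s <- par[1]; p <- par[2]
    m <- s * p / (1 - p); v <- s * p / (1 - p)^2
    est <- estimate_nb_moments(mean = m, variance = v)
    expect_equal(est$p, p, tolerance = 1e-12)
    expect_equal(est$s, s, tolerance = 1e-12)
  }

  expect_error(estimate_nb_moments(mean = 2, variance = 2), "overdispersed")
  expect_error(estimate_nb_moments(rep(1, 10)), "overdispersed")
})

test_that("moment estimator recovers NB parameters from draws", {
  withr::local_seed(7)
  x <- rnbinom(1e5, size = 3, prob = 0.6)  # our p = 0.4, s = 3
  est <- estimate_nb_moments(x)
  expect_lt(abs(est$p - 0.4), 0.02)
  expect_lt(abs(est$s - 3) / 3, 0.10)
})

test_that("zero-truncated fixed point solves the stated equations exactly", {
  # non-zero moments of NB(s=2, p=0.5): P(X=0)=0.25, E[X]=2, E[X^2]=8,
  # so NM1 = 2/0.75 = 8/3 and NM2 = 8/0.75 = 32/3
  for (init in list(NULL, 0, 0.9)) {
    bg <- estimate_nb_nonzero(nm1 = 8/3, nm2 = 32/3, p0_init = init,
                              tol = 1e-12)
    expect_equal(bg$p, 0.5, tolerance = 1e-8)
    expect_equal(bg$s, 2, tolerance = 1e-7)
    expect_equal(bg$p0, 0.25, tolerance = 1e-8)
    # the printed equations hold at the solution
    expect_equal(bg$p0, (1 - bg$p)^bg$s, tolerance = 1e-12)
    expect_equal(bg$p, 1 - (8/3) / (32/3 - (8/3)^2 * (1 - bg$p0)),
                 tolerance = 1e-8)
    expect_equal(bg$s, (8/3) * (1 - bg$p0) * (1 - bg$p) / bg$p,
                 tolerance = 1e-7)
  }
  expect_true(estimate_nb_nonzero(nm1 = 8/3, nm2 = 32/3)$zero_truncated)
  expect_error(estimate_nb_nonzero(rep(0, 100)), "non-zero")
})

test_that("zero-truncated estimator agrees with the full-moment estimator on draws", {
  withr::local_seed(11)
  x <- rnbinom(1e5, size = 2, prob = 0.5)  # our p = 0.5
  full <- estimate_nb_moments(x)
  trunc <- estimate_nb_nonzero(x)
  expect_lt(abs(trunc$p - 0.5), 0.02)
  expect_lt(abs(trunc$p - full$p), 0.03)
  expect_lt(abs(trunc$s - full$s) / full$s, 0.15)
  expect_lt(abs(trunc$p0 - mean(x == 0)), 0.02)
})

test_that("local control is the max of genome and window means", {
  # constant control: every window mean equals the constant
  const <- tiny_track(rep(3, 50))
  lc <- local_control(const)
  expect_equal(lc$r_ctrl, rep(3, 50))

  # single spike of 50 in one 200-bp bin among 100: genome mean 0.5,
  # 1 kb window (5 bins) 10, 5 kb (25 bins) 2, 10 kb (50 bins) 1
  v <- numeric(100); v[50] <- 50
  spike <- tiny_track(v)
  with_ctrl <- local_control(spike, has_control = TRUE)
  expect_equal(with_ctrl$r_ctrl[50], 10)
  # without a control the 1 kb window is dropped: max(0.5, 2, 1) = 2
  no_ctrl <- local_control(spike, has_control = FALSE)
  expect_equal(no_ctrl$r_ctrl[50], 2)
  # never below the genome-wide mean
  expect_true(all(with_ctrl$r_ctrl >= 0.5))
  expect_true(all(no_ctrl$r_ctrl >= 0.5))

  # windows truncate at chromosome ends: spike at bin 1
  v2 <- numeric(100); v2[1] <- 50
  edge <- local_control(tiny_track(v2), has_control = TRUE)
  # 5-bin window at the first bin truncates to bins 1..3: mean 50/3
  expect_equal(edge$r_ctrl[1], 50 / 3)
})

test_that("NB p-value track matches the geometric closed form and is monotone", {
  b <- tiny_bins(4)
  bg <- structure(list(p = 0.5, s = 1, p0 = 0.5, model = "nb", m_ctrl = 1,
                       zero_truncated = FALSE, iterations = 0L),
                  class = "nb_background")
  lc <- structure(list(r_ctrl = rep(1, 4), windows = integer(0),
                       has_control = TRUE, bins = b),
                  class = "local_control")
  # s_local = 1, p = 0.5: P(X >= k) = 0.5^k, so -log10 at x=10 is 10*log10(2)
  tr <- binned_track(b, c(0, 1, 10, 5))
  pv <- nb_pvalue_track(tr, lc, bg)
  expect_equal(pv$values[3], 10 * log10(2), tolerance = 1e-9)
  expect_identical(pv$values[1], 0)          # P(X >= 0) = 1
  expect_equal(pv$values[2], log10(2), tolerance = 1e-9)
  # non-decreasing in x at fixed (s_local, p)
  xs <- seq(0, 30, by = 0.25)
  pvx <- nb_pvalue_track(
    binned_track(tiny_bins(length(xs)), xs),
    structure(list(r_ctrl = rep(1, length(xs)), windows = integer(0),
                   has_control = TRUE, bins = tiny_bins(length(xs))),
              class = "local_control"),
    bg)
  expect_true(all(diff(pvx$values) >= 0))
})

test_that("NB tail converges to the Poisson tail as p -> 0 at fixed mean", {
  m <- 3; p <- 1e-6
  s <- m * (1 - p) / p
  for (x in c(2, 5, 9)) {
    nb_log <- pbeta(p, x, s, log.p = TRUE) / log(10)
    pois_log <- ppois(x - 1, m, lower.tail = FALSE, log.p = TRUE) / log(10)
    expect_equal(nb_log, pois_log, tolerance = 1e-4)
  }
})

test_that("p-value tracks are invariant under chromosome permutation", {
  withr::local_seed(3)
  sizes_ab <- c(chrA = 10000, chrB = 6000)
  ba <- make_bins(sizes_ab, 200)
  bb <- make_bins(rev(sizes_ab), 200)
  va <- rpois(n_bins(ba), 2); va[c(10, 40)] <- 60
  # same per-chromosome values, opposite chromosome order
  vb <- c(va[51:80], va[1:50])
  ta <- binned_track(ba, va); tb <- binned_track(bb, vb)
  mkbg <- function() structure(
    list(p = 0.4, s = 2, p0 = 0.6^2, model = "nb", m_ctrl = mean(va),
         zero_truncated = FALSE, iterations = 0L),
    class = "nb_background")
  pa <- nb_pvalue_track(ta, local_control(ta, has_control = FALSE), mkbg())
  pb <- nb_pvalue_track(tb, local_control(tb, has_control = FALSE), mkbg())
  expect_equal(pb$values, c(pa$values[51:80], pa$values[1:50]))
})

test_that("genome-wide fit supports trimming and the Poisson fallback", {
  withr::local_seed(5)
  # strong peaks contaminate the untrimmed fit; trimming restores it
  v <- rnbinom(5e4, size = 1, mu = 1/3)
  v[sample.int(5e4, 500)] <- rpois(500, 40)
  tr <- tiny_track(v)
  expect_error(fit_nb_background(tr), "heavy-tailed|collapsed")
  bg <- fit_nb_background(tr, trim = 0.01)
  expect_equal(bg$model, "nb")
  expect_lt(abs(bg$p - 0.25), 0.05)
  # near-Poisson counts have no NB solution; fallback substitutes Poisson
  vp <- rpois(2e4, 0.4)
  expect_error(fit_nb_background(tiny_track(vp)), "underdispersed|collapsed")
  bgp <- fit_nb_background(tiny_track(vp), fallback = "poisson")
  expect_equal(bgp$model, "poisson")
  expect_equal(bgp$lambda, mean(vp))
})
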