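# Dipolar kernel, background correction, non-negative Tikhonov inversion
# and distribution statistics.

test_that("kernel normalization, boundedness and quadrature accuracy", {
  expect_equal(dipolar_kernel(0, 3), 1)
  expect_equal(dipolar_kernel(0, 6), 1)
  tt <- seq(0, 2, by = 0.25)
  K <- dipolar_kernel(tt, c(3, 4, 5))
  expect_true(all(abs(K) <= 1 + 1e-12))
  # adaptive-quadrature oracle at t = 0.5 us, r = 4 nm
  w <- 2 * pi * 52.04 / 4^3
  oracle <- stats::integrate(function(x) cos((1 - 3 * x^2) * w * 0.5), 0, 1,
                             rel.tol = 1e-12)$value
  expect_equal(dipolar_kernel(0.5, 4), oracle, tolerance = 1e-6)
  expect_error(dipolar_kernel(0.5, -1), "positive")
})

test_that("background correction recovers the decay rate and depth", {
  dist <- gaussian_distribution(3, 0.25)
  tr <- generate_deer_trace(deer_trace_params(dist, t_max = 4,
                                              modulation_depth = 0.35,
                                              background_rate = 0.15))
  ff <- background_correct(tr)
  expect_equal(attr(ff, "background_rate"), 0.15, tolerance = 0.02)
  expect_equal(attr(ff, "modulation_depth"), 0.35, tolerance = 0.02)
  expect_equal(ff$F[1], 1)
  # d = 3 background is a plain exponential
  tr0 <- generate_deer_trace(deer_trace_params(dist, modulation_depth = 1e-9,
                                               background_rate = 0.2))
  expect_warning(background_correct(tr0), "modulation")
})

test_that("noiseless single-Gaussian form factors invert to the printed
           interspin distances", {
  for (center in c(3.3, 3.7)) {
    dist <- gaussian_distribution(center, 0.15)
    tr <- generate_deer_trace(deer_trace_params(dist, modulation_depth = 1,
                                                background_rate = 0))
    inv <- tikhonov_invert(data.frame(t = tr$t, F = tr$V))
    st <- distribution_stats(inv$distribution)
    expect_equal(st$mode, center, tolerance = 0.05)
    expect_equal(st$mean, center, tolerance = 0.05)
  }
})

test_that("solutions are non-negative, normalized, and L-curve is monotone", {
  dist <- gaussian_distribution(3.5, 0.2)
  tr <- generate_deer_trace(deer_trace_params(dist, modulation_depth = 1,
                                              background_rate = 0))
  inv <- tikhonov_invert(data.frame(t = tr$t, F = tr$V))
  p <- inv$distribution$p
  expect_true(all(p >= 0))
  expect_equal(ktrabtools:::trapz_int(inv$distribution$r, p), 1,
               tolerance = 1e-9)
  lc <- inv$lcurve   # alphas ascending: residual rises, seminorm falls
  expect_true(all(diff(lc$residual_norm) >= -1e-8))
  expect_true(all(diff(lc$seminorm) <= 1e-8))
})

test_that("two-Gaussian distribution at SNR 50 recovers both modes", {
  r <- seq(1.5, 8, by = 0.02)
  truth <- distance_distribution(r, 0.5 * stats::dnorm(r, 3, 0.12) +
                                    0.5 * stats::dnorm(r, 4, 0.12))
  tr <- generate_deer_trace(deer_trace_params(truth, modulation_depth = 0.4,
                                              background_rate = 0.05,
                                              noise_sd = 0.4 / 50, seed = 7))
  inv <- tikhonov_invert(background_correct(tr))
  p <- inv$distribution$p
  peaks <- r[which(diff(sign(diff(p))) == -2) + 1]
  peaks <- peaks[p[match(peaks, r)] > 0.2 * max(p)]
  expect_equal(length(peaks), 2L)
  expect_equal(peaks[1], 3.0, tolerance = 0.1)
  expect_equal(peaks[2], 4.0, tolerance = 0.1)
})

test_that("flat form factors are flagged as carrying no information", {
  flat <- data.frame(t = seq(0, 2, by = 0.05), F = rep(1, 41))
  expect_warning(tikhonov_invert(flat), "no dipolar modulation|flat")
})

test_that("fnnls equals the reference non-negative least squares", {
  set.seed(21)
  A <- matrix(rnorm(400), 40, 10); b <- rnorm(40)
  x1 <- ktrabtools:::fnnls(crossprod(A), drop(crossprod(A, b)))
  x2 <- pracma::lsqnonneg(A, b)$x
  expect_equal(x1, x2, tolerance = 1e-8)
  # warm start from a wrong support still reaches the same solution
  x3 <- ktrabtools:::fnnls(crossprod(A), drop(crossprod(A, b)),
                           P_init = c(rep(TRUE, 5), rep(FALSE, 5)))
  expect_equal(x3, x2, tolerance = 1e-8)
})

test_that("distribution statistics: mode, mean and width", {
  r <- seq(1.5, 8, by = 0.01)
  spike <- distance_distribution(r, stats::dnorm(r, 3.7, 0.02))
  st <- distribution_stats(spike)
  expect_equal(st$mode, 3.7, tolerance = 0.01)
  expect_equal(st$mean, 3.7, tolerance = 0.01)
  sym <- distance_distribution(r, stats::dnorm(r, 4, 0.3))
  st2 <- distribution_stats(sym)
  expect_equal(st2$mode, st2$mean, tolerance = 0.01)
  expect_equal(st2$width, 2 * 1.96 * 0.3, tolerance = 0.03)
  # bimodal, unequal masses: mean lies between modes, nearer the heavier
  bim <- distance_distribution(r, 0.7 * stats::dnorm(r, 3, 0.1) +
                                  0.3 * stats::dnorm(r, 5, 0.1))
  mu <- distribution_stats(bim)$mean
  expect_equal(mu, 0.7 * 3 + 0.3 * 5, tolerance = 0.01)
  expect_lt(abs(mu - 3), abs(mu - 5))
  expect_error(distribution_stats(data.frame(r = r, p = 0 * r)), "zero")
})
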