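# Generators: parameter validation, determinism, and the statistical
# structure the downstream analyses assume.

test_that("trajectory generator preserves frame count and validates input", {
  traj <- generate_idr_membrane_trajectory(
    toy_trajectory_params(n_frames = 100, seed = 2))
  expect_equal(n_frames(traj), 100)
  expect_error(toy_trajectory_params(n_frames = 0), "n_frames")
  expect_error(toy_trajectory_params(tail_length = 1), "tail_length")
})

test_that("identical seeds give bit-identical trajectories; seeds differ", {
  a <- generate_idr_membrane_trajectory(toy_trajectory_params(n_frames = 20, seed = 9))
  b <- generate_idr_membrane_trajectory(toy_trajectory_params(n_frames = 20, seed = 9))
  c <- generate_idr_membrane_trajectory(toy_trajectory_params(n_frames = 20, seed = 10))
  expect_identical(a$coords, b$coords)
  expect_false(identical(a$coords, c$coords))
})

test_that("generator calls do not disturb the caller's RNG stream", {
  set.seed(123); before <- runif(3)
  set.seed(123); invisible(generate_idr_membrane_trajectory(
    toy_trajectory_params(n_frames = 5, seed = 1)))
  after <- runif(3)
  expect_identical(before, after)
})

test_that("membrane affinity controls tail-lipid contact frequency", {
  lo <- generate_idr_membrane_trajectory(
    toy_trajectory_params(n_frames = 100, membrane_affinity = 0,
                          anchor_z = 30, seed = 3))
  hi <- generate_idr_membrane_trajectory(
    toy_trajectory_params(n_frames = 100, membrane_affinity = 50,
                          anchor_z = 30, seed = 3))
  frac <- function(traj)
    mean(lipid_contacts(traj, "2-21")$series$count > 0)
  expect_lt(frac(lo), 0.05)
  expect_gt(frac(hi), 0.9)
})

test_that("melt-curve generator is anchored at the stated Tm", {
  for (tm in c(67, 55)) {
    curve <- generate_melt_curve(melt_curve_params(tm = tm, noise_sd = 0))
    d <- diff(curve$fluorescence)
    mid <- (curve$temperature[-1] + curve$temperature[-nrow(curve)]) / 2
    # derivative peak of the noiseless sigmoid straddles tm symmetrically
    expect_equal(mean(mid[order(-d)[1:2]]), tm)
  }
  flat <- generate_melt_curve(melt_curve_params(baseline_low = 50,
                                                baseline_high = 50,
                                                noise_sd = 0))
  expect_true(all(abs(diff(flat$fluorescence)) < 1e-12))
  expect_error(melt_curve_params(t_range = numeric()), "non-empty")
})

test_that("thermogram generator obeys one-site limits", {
  zero <- generate_itc_thermogram(thermogram_params(dh = 0))
  expect_true(all(zero$heat == 0))
  weak <- suppressWarnings(
    generate_itc_thermogram(thermogram_params(kd = 1e7, dh = -10)))
  expect_true(all(abs(weak$heat) < 0.02))
  expect_true(all(diff(abs(weak$heat)) <= 1e-9))
  expect_warning(thermogram_params(syringe_conc = 0.1, cell_conc = 60),
                 "saturation")
})

test_that("uptake generator reproduces closed-form initial velocities", {
  S <- c(0.1, 0.2, 0.4, 1)
  kin <- generate_uptake_timecourses(
    uptake_params(vmax = 197, km = 0.2, substrate_concs = S, noise_sd = 0))
  expect_equal(kin$velocities$v, 197 * S / (0.2 + S))
  # half-saturation identity and the saturating limit
  kin2 <- generate_uptake_timecourses(
    uptake_params(vmax = 100, km = 0.5, substrate_concs = c(0.5, 5000)))
  expect_equal(kin2$velocities$v[1], 50)
  expect_equal(kin2$velocities$v[2], 100, tolerance = 1e-3)
  # linear early phase covers the 1-4 min points exactly
  tc <- kin$timecourses[["0.4"]]
  early <- tc$time <= 4
  expect_equal(tc$amount[early], kin$velocities$v[3] * tc$time[early])
  expect_error(uptake_params(substrate_concs = numeric()), "empty")
})

test_that("class-image generator records ground truth and fits the frame", {
  img <- generate_class_image(class_image_params(long_axis = 7.8,
                                                 short_axis = 6.3))
  expect_equal(img$truth$long_axis, 7.8)
  expect_true(all(img$pixels >= 0 & img$pixels <= 1))
  expect_error(class_image_params(long_axis = 20, image_size = 100,
                                  pixel_size = 0.05), "bounds")
  expect_error(class_image_params(long_axis = 5, short_axis = 6), "long_axis")
})

test_that("DEER trace generator satisfies V(0)=1 and the background limit", {
  dist <- gaussian_distribution(4, 0.3)
  tr <- generate_deer_trace(deer_trace_params(dist, modulation_depth = 0.4,
                                              background_rate = 0.3))
  expect_equal(tr$V[1], 1)
  tr0 <- generate_deer_trace(deer_trace_params(dist, modulation_depth = 1e-12,
                                               background_rate = 0.3))
  expect_equal(tr0$V, exp(-0.3 * tr0$t), tolerance = 1e-9)
  raw <- data.frame(r = dist$r, p = dist$p * 3)
  class(raw) <- c("distance_distribution", "data.frame")
  expect_error(deer_trace_params(raw), "normalized")
})

test_that("delta distribution produces the dipolar oscillation for 4 nm", {
  # single-distance form factor: compare against direct quadrature of the
  # kernel at r = 4 nm
  r <- seq(3.99, 4.01, by = 0.001)
  p <- rep(0, length(r)); p[11] <- 1
  dist <- distance_distribution(r, p)
  tr <- generate_deer_trace(deer_trace_params(dist, modulation_depth = 1,
                                              background_rate = 0))
  w <- 2 * pi * 52.04 / 4^3
  oracle <- vapply(tr$t, function(tt)
    stats::integrate(function(x) cos((1 - 3 * x^2) * w * tt), 0, 1,
                     rel.tol = 1e-10)$value, numeric(1))
  expect_equal(tr$V, oracle, tolerance = 1e-4)
})
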