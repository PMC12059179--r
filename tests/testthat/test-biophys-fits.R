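# DSF melting temperatures, one-site ITC fits and Michaelis-Menten
# kinetics: noiseless round trips and degenerate inputs.

test_that("melting temperature is read off the derivative peak", {
  for (tm in c(67, 55)) {
    curve <- generate_melt_curve(melt_curve_params(tm = tm, noise_sd = 0))
    expect_equal(melting_temperature(curve), tm, tolerance = 0.2)
  }
  # off-grid Tm still recovered by parabolic refinement
  curve <- generate_melt_curve(melt_curve_params(tm = 61.4, noise_sd = 0))
  expect_equal(melting_temperature(curve), 61.4, tolerance = 0.2)
})

test_that("flat curves raise a no-transition error", {
  flat <- generate_melt_curve(melt_curve_params(baseline_low = 50,
                                                baseline_high = 50))
  expect_error(melting_temperature(flat), "transition")
})

test_that("Tm is invariant under positive affine transforms of fluorescence", {
  curve <- generate_melt_curve(melt_curve_params(tm = 60, noise_sd = 0.5,
                                                 seed = 3))
  tm1 <- melting_temperature(curve)
  curve$fluorescence <- 3.7 * curve$fluorescence + 42
  expect_equal(melting_temperature(curve), tm1)
})

test_that("noiseless ITC thermograms refit to the generating K_D", {
  for (kd in c(3.4, 2.4)) {
    tg <- generate_itc_thermogram(thermogram_params(kd = kd, dh = -10))
    fit <- fit_one_site_itc(tg)
    expect_equal(fit$kd, kd, tolerance = 0.02)
    expect_equal(fit$dh, -10, tolerance = 0.02)
    expect_equal(fit$n_sites, 1, tolerance = 0.02)
  }
})

test_that("zero-heat thermograms raise a degenerate-fit error", {
  tg <- generate_itc_thermogram(thermogram_params(dh = 0))
  expect_error(fit_one_site_itc(tg), "degenerate")
})

test_that("ITC recovery error shrinks with the noise level", {
  err_at <- function(sd) {
    e <- vapply(1:20, function(s) {
      tg <- generate_itc_thermogram(thermogram_params(kd = 3.4, dh = -10,
                                                      noise_sd = sd, seed = s))
      abs(fit_one_site_itc(tg)$kd - 3.4) / 3.4
    }, numeric(1))
    stats::median(e)
  }
  expect_lt(err_at(0.02), err_at(0.4))
})

test_that("initial velocity recovers slopes and rejects short windows", {
  tc <- data.frame(time = c(1, 2, 3, 4, 7, 10),
                   amount = 10 * c(1, 2, 3, 4, 7, 10))
  expect_equal(initial_velocity(tc)$slope, 10)
  # saturating exponential A(1 - exp(-kt)) with initial slope A*k = 5
  tt <- seq(0.2, 2, by = 0.2)
  sat <- data.frame(time = tt, amount = 50 * (1 - exp(-0.1 * tt)))
  expect_equal(initial_velocity(sat, t_max = 2)$slope, 5, tolerance = 0.05)
  flat <- data.frame(time = 1:6, amount = rep(3, 6))
  expect_equal(initial_velocity(flat)$slope, 0)
  expect_error(initial_velocity(data.frame(time = 1:2, amount = 1:2)),
               "3 points")
})

test_that("Michaelis-Menten fit recovers printed kinetic parameters exactly", {
  S <- c(0.1, 0.2, 0.4, 1)
  for (vmax in c(197, 53)) {
    v <- vmax * S / (0.2 + S)
    fit <- fit_michaelis_menten(S, v)
    expect_equal(fit$vmax, vmax, tolerance = 1e-6)
    expect_equal(fit$km, 0.2, tolerance = 1e-6)
  }
  expect_error(fit_michaelis_menten(S, rep(0, 4)), "zero")
  expect_error(fit_michaelis_menten(c(1, 1, 1), c(1, 2, 3)), "distinct")
})

test_that("saturated velocities push Km to the boundary with a warning", {
  S <- c(0.1, 0.2, 0.4, 1)
  expect_warning(fit <- fit_michaelis_menten(S, rep(80, 4)), "boundary")
  expect_true(fit$boundary)
  expect_equal(fit$vmax, 80, tolerance = 1e-3)
})

test_that("full uptake round trip: time courses -> velocities -> kinetics", {
  p <- uptake_params(vmax = 197, km = 0.2)
  kin <- generate_uptake_timecourses(p)
  v <- vapply(kin$timecourses, function(tc) initial_velocity(tc)$slope,
              numeric(1))
  fit <- fit_michaelis_menten(p$substrate_concs, unname(v))
  expect_equal(fit$vmax, 197, tolerance = 1e-6)
  expect_equal(fit$km, 0.2, tolerance = 1e-6)
})

test_that("noisy-fit recovery improves monotonically as noise drops", {
  med_err <- function(sd) {
    e <- vapply(1:30, function(s) {
      kin <- generate_uptake_timecourses(
        uptake_params(vmax = 197, km = 0.2, noise_sd = sd, seed = s))
      v <- vapply(kin$timecourses,
                  function(tc) initial_velocity(tc)$slope, numeric(1))
      abs(fit_michaelis_menten(c(0.1, 0.2, 0.4, 1), unname(pmax(v, 0)))$vmax -
            197) / 197
    }, numeric(1))
    stats::median(e)
  }
  expect_lt(med_err(1), med_err(20))
})
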