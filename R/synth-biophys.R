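# Synthetic generators for the three biophysical assays: two-state thermal
# melts (differential scanning fluorimetry), one-site binding thermograms
# (isothermal titration calorimetry) and Michaelis-Menten whole-cell uptake
# time courses. Each generator shares its forward model with the matching
# fitting stage, so noiseless data round-trip exactly.

#' Parameters for a two-state melt curve
#'
#' @param tm melting temperature, degrees C (sigmoid inflection).
#' @param baseline_low,baseline_high fluorescence baselines (a.u.) below and
#'   above the transition.
#' @param slope transition width parameter in degrees C (> 0); the logistic
#'   scale parameter.
#' @param t_range strictly increasing temperature grid in degrees C
#'   (default 25-80 in 1 degree steps, the standard assay ramp).
#' @param noise_sd additive Gaussian noise sd (a.u.).
#' @param seed RNG seed.
#' @return List of class `melt_curve_params`.
#' @export
melt_curve_params <- function(tm = 67, baseline_low = 10, baseline_high = 100,
                              slope = 2, t_range = seq(25, 80, by = 1),
                              noise_sd = 0, seed = 1) {
  if (length(t_range) == 0L) stop_invalid("t_range must be non-empty")
  if (any(diff(t_range) <= 0)) stop_invalid("t_range must be strictly increasing")
  if (slope <= 0) stop_invalid("slope must be positive")
  structure(list(tm = tm, baseline_low = baseline_low,
                 baseline_high = baseline_high, slope = slope,
                 t_range = t_range, noise_sd = noise_sd, seed = seed),
            class = "melt_curve_params")
}

#' Generate a two-state melt curve
#'
#' Logistic sigmoid between the two baselines with inflection at `tm`:
#' F(T) = low + (high - low) / (1 + exp(-(T - tm)/slope)), plus optional
#' additive noise. Noiseless output is deterministic.
#'
#' @param params a [melt_curve_params()].
#' @return data.frame of class `melt_curve` with columns `temperature`,
#'   `fluorescence`.
#' @export
generate_melt_curve <- function(params) {
  if (!inherits(params, "melt_curve_params"))
    params <- do.call(melt_curve_params, params)
  p <- params
  f <- p$baseline_low + (p$baseline_high - p$baseline_low) /
    (1 + exp(-(p$t_range - p$tm) / p$slope))
  if (p$noise_sd > 0)
    f <- with_local_seed(p$seed, f + stats::rnorm(length(f), 0, p$noise_sd))
  out <- data.frame(temperature = p$t_range, fluorescence = f)
  class(out) <- c("melt_curve", "data.frame")
  out
}

#' Parameters for a one-site binding thermogram
#'
#' Defaults mirror the titration protocol: 20 injections of 2 uL into a
#' 280 uL cell.
#'
#' @param kd dissociation constant, uM.
#' @param dh binding enthalpy, kcal/mol.
#' @param n_sites stoichiometry (sites per macromolecule).
#' @param cell_conc macromolecule (site) concentration in the cell, uM.
#' @param syringe_conc ligand concentration in the syringe, uM.
#' @param n_injections number of injections (>= 2).
#' @param inj_volume injection volume, uL.
#' @param cell_volume cell volume, uL.
#' @param noise_sd additive noise on normalized heats (kcal/mol).
#' @param seed RNG seed.
#' @return List of class `thermogram_params`.
#' @export
thermogram_params <- function(kd = 3.4, dh = -10, n_sites = 1,
                              cell_conc = 60, syringe_conc = 800,
                              n_injections = 20, inj_volume = 2,
                              cell_volume = 280, noise_sd = 0, seed = 1) {
  if (kd <= 0 || cell_conc <= 0 || syringe_conc <= 0 || cell_volume <= 0 ||
      inj_volume <= 0)
    stop_invalid("concentrations, volumes and kd must be positive")
  if (n_injections < 2) stop_invalid("need at least 2 injections")
  if (syringe_conc <= cell_conc * n_sites / 100)
    warning("syringe concentration too low: titration never approaches saturation")
  structure(list(kd = kd, dh = dh, n_sites = n_sites, cell_conc = cell_conc,
                 syringe_conc = syringe_conc,
                 n_injections = as.integer(n_injections),
                 inj_volume = inj_volume, cell_volume = cell_volume,
                 noise_sd = noise_sd, seed = seed),
            class = "thermogram_params")
}

# Forward model of per-injection normalized heats (kcal per mole injectant).
# Exact well-mixed displacement dilution: after each injection of volume dV
# into cell volume V0, concentrations scale by (1 - dV/V0) and the injected
# ligand adds Xs * dV/V0. Bound concentration from the exact root of the
# one-site mass-balance quadratic. Injection heat = change of cell heat
# content, with the expelled volume carrying away its share.
itc_forward_heats <- function(kd, dh, n_sites, cell_conc, syringe_conc,
                              n_injections, inj_volume, cell_volume) {
  f <- inj_volume / cell_volume
  M <- cell_conc; X <- 0
  bound_prev <- 0
  q <- numeric(n_injections)
  for (i in seq_len(n_injections)) {
    M <- M * (1 - f)
    X <- X * (1 - f) + syringe_conc * f
    nM <- n_sites * M
    b <- nM + X + kd
    bound <- (b - sqrt(b^2 - 4 * nM * X)) / 2   # uM bound ligand
    # heat content is dh * bound * V0; the expelled volume carries away a
    # fraction f of the previous content; normalizing by moles injected
    # (syringe_conc * dV) leaves dh * delta_bound / (syringe_conc * f)
    q[i] <- dh * (bound - bound_prev * (1 - f)) / (syringe_conc * f)
    bound_prev <- bound
  }
  q
}

#' Generate a one-site ITC thermogram
#'
#' Per-injection heats from the exact single-site equilibrium binding
#' isotherm (mass-balance quadratic solved per injection, with well-mixed
#' displacement dilution), normalized per mole of injectant.
#'
#' @param params a [thermogram_params()].
#' @return data.frame of class `itc_thermogram` with columns `injection`,
#'   `volume` (uL), `heat` (kcal per mole injectant) and attributes carrying
#'   the cell geometry (`cell_conc`, `syringe_conc`, `cell_volume`).
#' @export
generate_itc_thermogram <- function(params) {
  if (!inherits(params, "thermogram_params"))
    params <- do.call(thermogram_params, params)
  p <- params
  q <- itc_forward_heats(p$kd, p$dh, p$n_sites, p$cell_conc, p$syringe_conc,
                         p$n_injections, p$inj_volume, p$cell_volume)
  if (p$noise_sd > 0)
    q <- with_local_seed(p$seed, q + stats::rnorm(length(q), 0, p$noise_sd))
  out <- data.frame(injection = seq_len(p$n_injections),
                    volume = rep(p$inj_volume, p$n_injections), heat = q)
  attr(out, "cell_conc") <- p$cell_conc
  attr(out, "syringe_conc") <- p$syringe_conc
  attr(out, "cell_volume") <- p$cell_volume
  class(out) <- c("itc_thermogram", "data.frame")
  out
}

#' Parameters for Michaelis-Menten uptake time courses
#'
#' Defaults mirror the whole-cell uptake assay: substrate (KCl) at 0.1, 0.2,
#' 0.4 and 1 mM, samples taken at 1, 2, 3, 4, 7 and 10 min.
#'
#' @param vmax maximal uptake velocity, nmol mg^-1 min^-1.
#' @param km Michaelis constant, mM.
#' @param substrate_concs substrate concentrations, mM.
#' @param timepoints sampling times, min.
#' @param noise_sd additive noise on amounts (nmol/mg).
#' @param seed RNG seed.
#' @return List of class `uptake_params`.
#' @export
uptake_params <- function(vmax = 197, km = 0.2,
                          substrate_concs = c(0.1, 0.2, 0.4, 1),
                          timepoints = c(1, 2, 3, 4, 7, 10),
                          noise_sd = 0, seed = 1) {
  if (vmax <= 0 || km <= 0) stop_invalid("vmax and km must be positive")
  if (length(substrate_concs) == 0L) stop_invalid("substrate list is empty")
  structure(list(vmax = vmax, km = km, substrate_concs = substrate_concs,
                 timepoints = timepoints, noise_sd = noise_sd, seed = seed),
            class = "uptake_params")
}

#' Generate Michaelis-Menten uptake time courses
#'
#' For each substrate concentration S the initial uptake velocity is the
#' Michaelis-Menten value v0 = Vmax * S / (Km + S). The intracellular amount
#' rises linearly (slope exactly v0) for the first 4 min and then
#' approaches a depletion-like plateau at 12 * v0 along a C1-continuous
#' exponential, so the default early-time window of the initial-velocity
#' fit is exactly linear on noiseless data.
#'
#' @param params an [uptake_params()].
#' @return List of class `kinetic_dataset` with `velocities` (data.frame
#'   `S`, `v`: exact initial velocities) and `timecourses` (list per S of
#'   data.frames `time`, `amount`).
#' @export
generate_uptake_timecourses <- function(params) {
  if (!inherits(params, "uptake_params"))
    params <- do.call(uptake_params, params)
  p <- params
  v0 <- p$vmax * p$substrate_concs / (p$km + p$substrate_concs)
  t_lin <- 4; cap_mult <- 12
  tc <- lapply(seq_along(p$substrate_concs), function(k) {
    v <- v0[k]; cap <- cap_mult * v
    amt <- ifelse(p$timepoints <= t_lin, v * p$timepoints,
                  v * t_lin + (cap - v * t_lin) *
                    (1 - exp(-v * (p$timepoints - t_lin) / (cap - v * t_lin))))
    data.frame(time = p$timepoints, amount = amt)
  })
  names(tc) <- as.character(p$substrate_concs)
  if (p$noise_sd > 0) {
    tc <- with_local_seed(p$seed, lapply(tc, function(d) {
      d$amount <- d$amount + stats::rnorm(nrow(d), 0, p$noise_sd)
      d
    }))
  }
  structure(list(velocities = data.frame(S = p$substrate_concs, v = v0),
                 timecourses = tc),
            class = "kinetic_dataset")
}
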