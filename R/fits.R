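# Curve-fitting stages: melting-temperature extraction from the first
# derivative of a melt curve, least-squares fit of the one-site binding
# isotherm to an ITC thermogram, and Michaelis-Menten kinetics from initial
# uptake velocities.

#' Melting temperature from the first-derivative peak
#'
#' The melting point is read off as the peak of the (smoothed) first
#' derivative of fluorescence with respect to temperature, refined by
#' parabolic interpolation through the discrete maximum. Smoothing is a
#' centered Savitzky-Golay filter (quadratic, 5-point window by default on
#' the 1 degree grid). The estimate is invariant under positive affine
#' transforms of the fluorescence.
#'
#' @param curve a `melt_curve` data.frame (`temperature`, `fluorescence`).
#' @param window odd integer smoothing window (points); 1 disables
#'   smoothing.
#' @return Tm in degrees C.
#' @export
melting_temperature <- function(curve, window = 5) {
  t <- curve$temperature; f <- curve$fluorescence
  if (length(t) < 5L) stop_invalid("need at least 5 points across the transition")
  d <- diff(f) / diff(t)
  tm_grid <- (t[-1] + t[-length(t)]) / 2
  if (window > 1 && length(d) >= window)
    d <- signal::sgolayfilt(d, p = 2, n = window)
  span <- diff(range(f))
  if (span <= 0 || max(d) <= 1e-9 * max(span, 1))
    stop_invalid("no melting transition detected (derivative never positive)")
  parabolic_peak(tm_grid, d)
}

#' Fit the one-site binding isotherm to an ITC thermogram
#'
#' Nonlinear least squares of the exact single-site mass-balance model
#' (same forward model as [generate_itc_thermogram()]) for K_D, the binding
#' enthalpy and the stoichiometry. K_D is optimized on a log scale for
#' conditioning; the initializer places K_D near the titration midpoint
#' inflection.
#'
#' @param thermogram an `itc_thermogram` (or a data.frame with `heat`, plus
#'   `cell_conc`, `syringe_conc`, `cell_volume`, `inj_volume` given
#'   explicitly).
#' @param cell_conc,syringe_conc,cell_volume,inj_volume cell geometry; taken
#'   from the thermogram attributes when present.
#' @param fit_n also fit the stoichiometry (default TRUE).
#' @return List of class `binding_fit` with `kd` (uM), `dh` (kcal/mol),
#'   `n_sites`, `residual_norm` and the `fit` object.
#' @export
fit_one_site_itc <- function(thermogram, cell_conc = NULL,
                             syringe_conc = NULL, cell_volume = NULL,
                             inj_volume = NULL, fit_n = TRUE) {
  q <- thermogram$heat
  cell_conc <- cell_conc %||% attr(thermogram, "cell_conc")
  syringe_conc <- syringe_conc %||% attr(thermogram, "syringe_conc")
  cell_volume <- cell_volume %||% attr(thermogram, "cell_volume")
  inj_volume <- inj_volume %||% thermogram$volume[1]
  if (is.null(cell_conc) || is.null(syringe_conc) || is.null(cell_volume))
    stop_invalid("cell geometry (cell_conc, syringe_conc, cell_volume) required")
  if (max(abs(q)) < 1e-9)
    stop_invalid("degenerate fit: total heat is (near) zero")
  n_inj <- length(q)

  fwd <- function(log_kd, dh, n) {
    itc_forward_heats(exp(log_kd), dh, n, cell_conc, syringe_conc,
                      n_inj, inj_volume, cell_volume)
  }
  # initializer: dh from the first (most saturating) heats, kd midpoint at
  # molar ratio ~ n, i.e. a c-value of order 10
  dh0 <- q[1]
  kd0 <- max(cell_conc / 10, 1e-3)
  df <- data.frame(idx = seq_len(n_inj), q = q)
  fit <- tryCatch({
    if (fit_n)
      minpack.lm::nlsLM(q ~ fwd(log_kd, dh, n), data = df,
                        start = list(log_kd = log(kd0), dh = dh0, n = 1),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    else
      minpack.lm::nlsLM(q ~ fwd(log_kd, dh, 1), data = df,
                        start = list(log_kd = log(kd0), dh = dh0),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
  }, error = function(e)
    stop_invalid("one-site fit failed to converge: ", conditionMessage(e)))
  cf <- stats::coef(fit)
  structure(list(kd = unname(exp(cf["log_kd"])), dh = unname(cf["dh"]),
                 n_sites = if (fit_n) unname(cf["n"]) else 1,
                 residual_norm = sqrt(sum(stats::resid(fit)^2)),
                 fit = fit),
            class = "binding_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Initial uptake velocity from a time course
#'
#' Ordinary least-squares slope over the configured early-time window. The
#' default window keeps points up to 4 min (the assay samples at 1, 2, 3,
#' 4, 7, 10 min) or points before 50% of the plateau, whichever gives
#' fewer, but never fewer than 3 points.
#'
#' @param time,amount numeric vectors (min, nmol/mg), or a data.frame with
#'   those columns as first argument.
#' @param t_max latest time included in the window (min).
#' @param plateau_frac drop points above this fraction of the final amount.
#' @return List with `slope` (nmol mg^-1 min^-1), `se` (standard error; NA
#'   for an exact 2-parameter fit through collinear points).
#' @export
initial_velocity <- function(time, amount = NULL, t_max = 4,
                             plateau_frac = 0.5) {
  if (is.data.frame(time)) { amount <- time$amount; time <- time$time }
  keep <- time <= t_max
  plateau <- max(amount)
  keep2 <- keep & (amount <= plateau_frac * plateau | plateau <= 0)
  if (sum(keep2) >= 3) keep <- keep2
  if (sum(keep) < 3L) stop_invalid("fewer than 3 points in the early window")
  fit <- stats::lm(amount[keep] ~ time[keep])
  # noiseless courses are exactly collinear; the se is then meaningless
  sm <- suppressWarnings(summary(fit))$coefficients
  list(slope = unname(sm[2, 1]), se = unname(sm[2, 2]))
}

#' Fit Michaelis-Menten kinetics to initial velocities
#'
#' Nonlinear least squares of v = Vmax * S / (Km + S). Unweighted by
#' default; supply `weights` (e.g. inverse variances) to weight points.
#'
#' @param S substrate concentrations (mM), or a data.frame with columns
#'   `S`, `v` (and optionally `w`).
#' @param v initial velocities (nmol mg^-1 min^-1, >= 0).
#' @param weights optional fit weights.
#' @return List of class `mm_fit` with `vmax`, `km`, their standard errors
#'   (`vmax_se`, `km_se`), `boundary` (TRUE when the fit collapsed to the
#'   saturated Km -> 0 limit) and the `fit` object.
#' @export
#' @examples
#' v <- 197 * c(0.1, 0.2, 0.4, 1) / (0.2 + c(0.1, 0.2, 0.4, 1))
#' fit_michaelis_menten(c(0.1, 0.2, 0.4, 1), v)$vmax
fit_michaelis_menten <- function(S, v = NULL, weights = NULL) {
  if (is.data.frame(S)) { v <- S$v; weights <- S$w %||% weights; S <- S$S }
  if (length(unique(S)) < 2L) stop_invalid("need >= 2 distinct substrate levels")
  if (all(v == 0)) stop_invalid("all velocities are zero")
  if (any(v < 0)) stop_invalid("velocities must be non-negative")
  df <- data.frame(S = S, v = v)
  # saturated limit: equal velocities at every S carry no Km information;
  # the least-squares solution is Vmax = mean(v), Km -> 0
  if (diff(range(v)) < 1e-9 * max(v)) {
    warning("Km at the zero boundary: velocities are saturated; Vmax ~ mean(v)")
    return(structure(list(vmax = mean(v), km = 0, vmax_se = NA_real_,
                          km_se = NA_real_, boundary = TRUE, fit = NULL),
                     class = "mm_fit"))
  }
  # Lineweaver-Burk initializer guarded against zero velocities
  pos <- v > 0
  lb <- stats::lm(I(1 / v[pos]) ~ I(1 / S[pos]))
  vmax0 <- unname(1 / stats::coef(lb)[1])
  km0 <- unname(stats::coef(lb)[2] * vmax0)
  if (!is.finite(vmax0) || vmax0 <= 0) vmax0 <- max(v) * 1.5
  if (!is.finite(km0) || km0 <= 0) km0 <- stats::median(S)
  args <- list(v ~ Vmax * S / (Km + S), data = df,
               start = list(Vmax = vmax0, Km = km0), lower = c(0, 0),
               control = minpack.lm::nls.lm.control(maxiter = 200))
  if (!is.null(weights)) args$weights <- weights
  fit <- tryCatch(
    do.call(minpack.lm::nlsLM, args),
    error = function(e)
      stop_invalid("Michaelis-Menten fit failed: ", conditionMessage(e),
                   " (starts Vmax=", signif(vmax0, 3), ", Km=",
                   signif(km0, 3), ")"))
  cf <- stats::coef(fit)
  sm <- tryCatch(summary(fit)$coefficients, error = function(e) NULL)
  boundary <- cf["Km"] < 1e-6 * stats::median(S)
  if (boundary)
    warning("Km at the zero boundary: velocities are saturated; Vmax ~ mean(v)")
  structure(list(vmax = unname(cf["Vmax"]), km = unname(cf["Km"]),
                 vmax_se = if (is.null(sm)) NA_real_ else sm["Vmax", 2],
                 km_se = if (is.null(sm)) NA_real_ else sm["Km", 2],
                 boundary = boundary, fit = fit),
            class = "mm_fit")
}
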