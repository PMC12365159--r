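## Big-leaf surface scheme: canopy-surface concentration from flux and
## resistances, ideal-gas vapour pressures, Clausius-Clapeyron saturation
## pressure, the surface availability ratio r = p_vap(z0)/p_sat(T_air) and
## its fitted double-exponential dynamics, the flux modelled from the fit,
## and gap-filled cumulative volatilisation.

#' Physical constants for chlorothalonil vapour calculations
#'
#' The printed value of the gas constant in some sources of this scheme is a
#' typographical slip; the standard R = 8.314 J mol-1 K-1 is used for the
#' ideal-gas conversion, while the Clausius-Clapeyron fit keeps its own
#' fitted constant of 8.3 J mol-1 K-1.
#'
#' @format list with `molar_mass` (g mol-1), `gas_const` (J mol-1 K-1).
#' @export
chlorothalonil <- list(molar_mass = 265.911, gas_const = 8.314)

#' Canopy-surface concentration from flux and resistances
#'
#' \eqn{C(z_0) = C(z_{ref}) + F (R_b + R_a(z_{ref}))}; the exact inverse of
#' the big-leaf resistance flux equation.
#'
#' @param c_ref concentration at the reference height, ng m-3.
#' @param flux volatilisation flux, ng m-2 s-1 (emission positive).
#' @param r_a aerodynamic resistance, s m-1.
#' @param r_b quasi-laminar boundary-layer resistance, s m-1.
#' @return surface concentration, ng m-3.
#' @export
surface_concentration <- function(c_ref, flux, r_a, r_b) {
  c_ref + flux * (r_b + r_a)
}

#' Big-leaf resistance flux
#'
#' \eqn{F = (C(z_0) - C(z_{ref}))/(R_b + R_a(z_{ref}))}; mutual inverse of
#' [surface_concentration()].
#'
#' @param c_z0 canopy-surface concentration, ng m-3.
#' @inheritParams surface_concentration
#' @return flux, ng m-2 s-1 (emission positive).
#' @export
resistance_flux <- function(c_z0, c_ref, r_a, r_b) {
  (c_z0 - c_ref) / (r_b + r_a)
}

#' Ideal-gas vapour pressure of an airborne concentration
#'
#' \eqn{p_{vap} = C \times 10^{-9} R (T_{air}+273.15)/M}.
#'
#' @param conc concentration, ng m-3 (>= 0).
#' @param t_air air temperature, degC.
#' @param molar_mass molar mass, g mol-1.
#' @return partial pressure, Pa.
#' @export
vapour_pressure <- function(conc, t_air,
                            molar_mass = chlorothalonil$molar_mass) {
  conc * 1e-9 * chlorothalonil$gas_const * (t_air + 273.15) / molar_mass
}

#' Concentration corresponding to a vapour pressure (inverse of Eq. above)
#'
#' @param p_vap partial pressure, Pa.
#' @inheritParams vapour_pressure
#' @return concentration, ng m-3.
#' @export
conc_from_vapour_pressure <- function(p_vap, t_air,
                                      molar_mass = chlorothalonil$molar_mass) {
  p_vap * molar_mass / (chlorothalonil$gas_const * (t_air + 273.15)) * 1e9
}

#' Clausius-Clapeyron saturation vapour pressure
#'
#' \eqn{p_{sat}(T) = p_{ref} \exp[(E_a/R_{fit})(1/T_{ref,K} - 1/T_K)]},
#' with the chlorothalonil reference point \eqn{7.6\times10^{-5}} Pa at
#' 25 degC and activation energy 95000 J mol-1 (fitted constant 8.3).
#'
#' @param t_air air temperature, degC (> -100).
#' @param p_ref saturation pressure at `t_ref`, Pa.
#' @param t_ref reference temperature, degC.
#' @param activation activation energy, J mol-1.
#' @param gas_const_fit gas constant as used in the fitted expression,
#'   J mol-1 K-1.
#' @return saturation pressure, Pa; strictly increasing in `t_air`.
#' @export
#' @examples
#' saturation_pressure(25)   # reference point
saturation_pressure <- function(t_air, p_ref = 7.6e-5, t_ref = 25,
                                activation = 95000, gas_const_fit = 8.3) {
  stopifnot(all(t_air > -100, na.rm = TRUE), p_ref > 0)
  p_ref * exp(activation / gas_const_fit *
                (1 / (t_ref + 273.15) - 1 / (t_air + 273.15)))
}

#' Surface availability ratio
#'
#' \eqn{r = p_{vap}(z_0)/p_{sat}(T_{air})}: interpreted as the fraction of
#' the canopy and ground surface covered by unbound (transfer-available)
#' compound.
#'
#' @param p_vap_z0 surface vapour pressure, Pa.
#' @param p_sat saturation vapour pressure, Pa (> 0).
#' @return dimensionless ratio >= 0.
#' @export
availability_ratio <- function(p_vap_z0, p_sat) {
  stopifnot(all(p_sat > 0, na.rm = TRUE))
  p_vap_z0 / p_sat
}

#' Per-step surface state from measured concentration and flux
#'
#' Combines the resistance scheme and vapour-pressure conversions into the
#' per-step surface state: resistances, surface concentration, vapour
#' pressures, saturation pressure and availability ratio.
#'
#' @param met validated met data.frame.
#' @param conc receptor concentration at `z_ref`, ng m-3.
#' @param flux volatilisation flux, ng m-2 s-1.
#' @param z_ref measurement height, m.
#' @param ... stability options passed to the resistance functions.
#' @return data.frame `timestamp, r_a, r_b, c_z0, p_vap_ref, p_vap_z0,
#'   p_sat, r`.
#' @export
surface_state <- function(met, conc, flux, z_ref = 1.9, ...) {
  z0 <- if (!is.null(met$z0)) met$z0 else 0.0035
  d <- if (!is.null(met$d)) met$d else 2 / 3 * met$h_c
  r_a <- aerodynamic_resistance(z_ref, met$ustar, met$obukhov_l, z0, d, ...)
  r_b <- boundary_layer_resistance(met$ustar)
  c_z0 <- surface_concentration(conc, flux, r_a, r_b)
  p_sat <- saturation_pressure(met$t_air)
  data.frame(
    timestamp = met$timestamp, r_a = r_a, r_b = r_b, c_z0 = c_z0,
    p_vap_ref = vapour_pressure(conc, met$t_air),
    p_vap_z0 = vapour_pressure(c_z0, met$t_air),
    p_sat = p_sat,
    r = availability_ratio(vapour_pressure(c_z0, met$t_air), p_sat)
  )
}

#' Aggregate the availability ratio to daily values
#'
#' Nighttime resistances are the noisiest part of the chain, so the daily
#' ratio is taken over a configurable daytime window by default.
#'
#' @param timestamp POSIXct vector.
#' @param r per-step availability ratio.
#' @param day_origin time origin used to count days (default first
#'   timestamp).
#' @param hours UTC hour window retained (default 9--16).
#' @return data.frame `day` (days since origin, at window centre) and `r`.
#' @export
daily_availability <- function(timestamp, r, day_origin = NULL,
                               hours = c(9, 16)) {
  if (is.null(day_origin)) day_origin <- min(timestamp, na.rm = TRUE)
  hr <- as.numeric(format(timestamp, "%H", tz = "UTC")) +
    as.numeric(format(timestamp, "%M", tz = "UTC")) / 60
  keep <- hr >= hours[1] & hr <= hours[2] & !is.na(r)
  dd <- floor(as.numeric(difftime(timestamp, day_origin, units = "days")))
  agg <- tapply(r[keep], dd[keep], stats::median, na.rm = TRUE)
  data.frame(day = as.numeric(names(agg)) + mean(hours) / 24,
             r = as.numeric(agg))
}

#' Fit double-exponential availability dynamics
#'
#' Nonlinear least squares of \eqn{y(t) = a_1 e^{-k_1 t} + a_2 e^{-k_2 t}}
#' against a daily availability-ratio (or remaining-content) series. With
#' `fix_k2 = 0` the second term becomes a plateau
#' (\eqn{y = a_1 e^{-k_1 t} + a_2}).
#'
#' @param day time since application, days (>= 8 points).
#' @param y series to fit; if `normalise = TRUE` it is rescaled to
#'   100 * y/max(y) before fitting so the amplitudes read as percent of the
#'   initial value.
#' @param fix_k2 `NULL` (free) or a fixed value for the slow rate constant.
#' @param normalise logical.
#' @param start optional named start values (`a1`, `k1`, `a2`, `k2`).
#' @return object of class `availability_fit`: coefficients, standard
#'   errors, convergence info, fitted values and a `predict` closure.
#' @export
fit_availability <- function(day, y, fix_k2 = NULL, normalise = FALSE,
                             start = NULL) {
  ok <- !is.na(day) & !is.na(y)
  day <- day[ok]; y <- y[ok]
  if (length(y) < 8) stop("fit_availability needs at least 8 daily points")
  scale0 <- max(y)
  if (normalise) y <- 100 * y / scale0
  y0 <- max(y)
  if (is.null(start))
    start <- list(a1 = 0.55 * y0, k1 = 0.5, a2 = 0.45 * y0, k2 = 0.01)
  df <- data.frame(t = day, y = y)
  fit <- if (is.null(fix_k2)) {
    minpack.lm::nlsLM(y ~ a1 * exp(-k1 * t) + a2 * exp(-k2 * t), data = df,
                      start = start,
                      lower = c(0, 0, 0, 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200))
  } else {
    k2fix <- fix_k2
    minpack.lm::nlsLM(y ~ a1 * exp(-k1 * t) + a2 * exp(-k2fix * t), data = df,
                      start = start[c("a1", "k1", "a2")],
                      lower = c(0, 0, 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200))
  }
  sm <- summary(fit)
  co <- stats::coef(fit)
  if (!is.null(fix_k2)) co <- c(co, k2 = fix_k2)
  se <- sm$coefficients[, "Std. Error"]
  if (!is.null(fix_k2)) se <- c(se, k2 = 0)
  conv <- fit$convInfo
  if (!isTRUE(conv$isConv))
    warning("availability fit did not converge: ", conv$stopMessage)
  structure(list(
    coefficients = co[c("a1", "k1", "a2", "k2")],
    std_errors = se[c("a1", "k1", "a2", "k2")],
    converged = isTRUE(conv$isConv),
    message = conv$stopMessage, iterations = conv$finIter,
    sigma = sm$sigma, n = length(y), normalise = normalise,
    scale0 = scale0, fitted = stats::fitted(fit)
  ), class = "availability_fit")
}

#' @export
print.availability_fit <- function(x, ...) {
  co <- x$coefficients; se <- x$std_errors
  cat("Double-exponential availability fit\n")
  cat(sprintf("  y = %.3g exp(-%.3g t) + %.3g exp(-%.3g t)\n",
              co["a1"], co["k1"], co["a2"], co["k2"]))
  cat(sprintf("  SEs: a1 %.2g, k1 %.2g, a2 %.2g, k2 %.2g; n = %d; %s\n",
              se["a1"], se["k1"], se["a2"], se["k2"], x$n,
              if (x$converged) "converged" else "NOT CONVERGED"))
  invisible(x)
}

#' Predict an availability fit at given times
#'
#' @param object an `availability_fit`.
#' @param day times in days.
#' @param rescale if the fit was normalised, multiply back to the original
#'   scale (default TRUE).
#' @param ... unused.
#' @return fitted values.
#' @export
predict.availability_fit <- function(object, day, rescale = TRUE, ...) {
  co <- object$coefficients
  y <- co["a1"] * exp(-co["k1"] * day) + co["a2"] * exp(-co["k2"] * day)
  if (object$normalise && rescale) y <- y * object$scale0 / 100
  unname(y)
}

#' Flux modelled from fitted availability dynamics
#'
#' Reconstructs the surface concentration from the fitted ratio,
#' \eqn{C(z_0) = r(t)\, p_{sat}(T_{air}) M/(R T_K) \times 10^9}, and the flux
#' through the resistances, \eqn{F = (C(z_0) - C(z_{ref}))/(R_b + R_a)}.
#'
#' @param fit an `availability_fit` (on the ratio scale) or a function
#'   `r(day)`.
#' @param met validated met data.frame.
#' @param conc_ref concentration at the reference height, ng m-3 (scalar or
#'   vector); the ambient term in the resistance equation.
#' @param day time since application in days for each met row.
#' @param z_ref measurement height, m.
#' @param ... stability options.
#' @return data.frame `timestamp, flux, method = "modelled"`.
#' @export
modelled_flux <- function(fit, met, conc_ref, day, z_ref = 1.9, ...) {
  r_t <- if (is.function(fit)) fit(day) else predict(fit, day)
  z0 <- if (!is.null(met$z0)) met$z0 else 0.0035
  d <- if (!is.null(met$d)) met$d else 2 / 3 * met$h_c
  r_a <- aerodynamic_resistance(z_ref, met$ustar, met$obukhov_l, z0, d, ...)
  r_b <- boundary_layer_resistance(met$ustar)
  c_z0 <- conc_from_vapour_pressure(
    r_t * saturation_pressure(met$t_air), met$t_air)
  data.frame(timestamp = met$timestamp,
             flux = resistance_flux(c_z0, rep_len(conc_ref, nrow(met)),
                                    r_a, r_b),
             method = "modelled")
}

## 1 g ha-1 = 1e9 ng / 1e4 m2 = 1e5 ng m-2
NG_M2_PER_G_HA <- 1e5

#' Gap-fill a measured flux series with a rescaled modelled flux
#'
#' Within a moving window (default 7 days) the modelled flux is linearly
#' rescaled (zero-intercept least squares) to the measured flux over the
#' steps where both exist; masked steps are then filled with the rescaled
#' model. Windows with insufficient overlap fall back to the nearest window
#' with a fitted scale (recorded in the output).
#'
#' @param timestamp POSIXct, 30-min grid.
#' @param measured measured flux, ng m-2 s-1, NA where masked.
#' @param modelled modelled flux on the same grid.
#' @param window_days moving-window width, days.
#' @param min_overlap minimum fraction of window steps with both series
#'   present for a direct fit (default 0.5).
#' @return data.frame `timestamp, flux, method` (`measured` or `gapfilled`),
#'   `scale` (window scale factor applied to filled steps).
#' @export
gapfill_flux <- function(timestamp, measured, modelled, window_days = 7,
                         min_overlap = 0.5) {
  n <- length(measured)
  tnum <- as.numeric(timestamp)
  half <- window_days * 86400 / 2
  need <- which(is.na(measured))
  ## per-day window scales
  days <- floor((tnum - tnum[1]) / 86400)
  uday <- sort(unique(days))
  scl <- rep(NA_real_, length(uday))
  for (i in seq_along(uday)) {
    ctr <- tnum[1] + (uday[i] + 0.5) * 86400
    inw <- tnum >= ctr - half & tnum <= ctr + half
    both <- inw & !is.na(measured) & !is.na(modelled)
    if (sum(both) >= min_overlap * sum(inw) && sum(both) >= 4 &&
        sum(modelled[both]^2) > 0)
      scl[i] <- sum(measured[both] * modelled[both]) / sum(modelled[both]^2)
  }
  if (all(is.na(scl))) stop("no window with enough measured/modelled overlap")
  ## nearest fitted window fallback
  fitted_idx <- which(!is.na(scl))
  for (i in seq_along(uday)) {
    if (is.na(scl[i]))
      scl[i] <- scl[fitted_idx[which.min(abs(fitted_idx - i))]]
  }
  flux <- measured
  method <- ifelse(is.na(measured), "gapfilled", "measured")
  scale_col <- rep(1, n)
  di <- match(days, uday)
  fillable <- need[!is.na(modelled[need])]
  flux[fillable] <- scl[di[fillable]] * modelled[fillable]
  scale_col[fillable] <- scl[di[fillable]]
  data.frame(timestamp = timestamp, flux = flux, method = method,
             scale = scale_col)
}

#' Cumulative volatilised fraction of the applied dose
#'
#' Trapezoidal time integration of the flux, expressed in percent of the
#' applied dose (1 g ha-1 = 1e5 ng m-2).
#'
#' @param timestamp POSIXct grid.
#' @param flux flux series, ng m-2 s-1 (NA treated as 0 with a warning
#'   unless `na_zero = FALSE`).
#' @param dose_g_per_ha applied dose, g ha-1.
#' @param na_zero replace NA by 0 before integrating.
#' @return data.frame `timestamp, cum_pct` (non-decreasing for non-negative
#'   fluxes).
#' @export
cumulate_flux <- function(timestamp, flux, dose_g_per_ha = 544,
                          na_zero = TRUE) {
  if (any(is.na(flux))) {
    if (!na_zero) stop("flux contains NA; gap-fill first")
    flux[is.na(flux)] <- 0
  }
  tnum <- as.numeric(timestamp)
  dt <- diff(tnum)
  inc <- c(0, (flux[-1] + flux[-length(flux)]) / 2 * dt)
  cum_ng_m2 <- cumsum(inc)
  data.frame(timestamp = timestamp,
             cum_pct = 100 * cum_ng_m2 / (dose_g_per_ha * NG_M2_PER_G_HA))
}

#' Gap-fill and cumulate in one call
#'
#' @inheritParams gapfill_flux
#' @inheritParams cumulate_flux
#' @return list with `filled` (gap-filled series) and `cumulative`
#'   (data.frame of cumulative percent of dose).
#' @export
gapfill_and_cumulate <- function(timestamp, measured, modelled,
                                 dose_g_per_ha = 544, window_days = 7,
                                 min_overlap = 0.5) {
  filled <- gapfill_flux(timestamp, measured, modelled, window_days,
                         min_overlap)
  cum <- cumulate_flux(timestamp, filled$flux, dose_g_per_ha)
  list(filled = filled, cumulative = cum)
}

#' First-order dissipation budget of the surface availability
#'
#' Sums independent first-order dissipation pathways (photodegradation, leaf
#' penetration, volatilisation; all day-1) for comparison with the fitted
#' fast decay rate of the availability ratio. Literature values for
#' chlorothalonil are 0.14 day-1 (photodegradation) and 0.23 day-1 (leaf
#' penetration); the volatilisation constant is obtained by fitting the
#' remaining-content series, e.g. with [fit_availability()] and `fix_k2 = 0`.
#'
#' @param photodegradation,penetration,volatilisation rate constants, day-1.
#' @return list with `components` and `total` (day-1).
#' @export
dissipation_budget <- function(photodegradation = 0.14, penetration = 0.23,
                               volatilisation = 0.20) {
  comp <- c(photodegradation = photodegradation, penetration = penetration,
            volatilisation = volatilisation)
  if (any(comp < 0)) stop("rate constants must be >= 0")
  list(components = comp, total = sum(comp))
}
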