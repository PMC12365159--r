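## Synthetic campaign generator: diurnal micromet cycles, a surface
## availability ratio decaying as a double exponential, the resulting truth
## flux through the resistance + dispersion physics, noisy receptor and
## gradient observations with outages, and filter-dose observations.

#' Campaign configuration
#'
#' Defaults emulate a three-week spring volatilisation campaign over a
#' treated winter-wheat field: 30-min records, one pre-application day, a
#' 544 g ha-1 application, availability decaying as
#' 57 exp(-0.61 t) + 43 exp(-0.012 t) percent of an initial surface
#' saturation ratio of 0.18, receptor at 1.9 m located 40 m inside a 20-ha
#' field, gradient levels at 0.63/1.23/2.03 m, 14 percent concentration
#' noise, a background of 5.7 +/- 2.2 ng m-3, and two instrument outages.
#'
#' @param n_days campaign length, days (>= 2).
#' @param dt_min time step, minutes.
#' @param application_day day index of the application (days after campaign
#'   start; earlier steps are pre-application background).
#' @param dose_g_per_ha applied dose.
#' @param r0 availability ratio just after application.
#' @param avail_truth named vector `a1, k1, a2, k2` (percent amplitudes and
#'   day-1 rates) of the availability decay.
#' @param ustar_night,ustar_day friction-velocity bounds of the diurnal
#'   cycle, m s-1.
#' @param t_mean,t_amp air-temperature mean and diurnal amplitude, degC.
#' @param wd_mean,wd_sd wind-direction mean and per-step sd, deg/N.
#' @param l_day,l_night typical daytime (negative) and nighttime (positive)
#'   Obukhov lengths, m.
#' @param conc_noise multiplicative concentration noise (fraction).
#' @param gradient_noise multiplicative noise on gradient-level samples.
#' @param c_bgd_mean,c_bgd_sd background concentration, ng m-3.
#' @param filter_cv coefficient of variation of filter doses.
#' @param ground_frac fraction of the applied dose reaching the ground.
#' @param outages list of `c(start_day, end_day)` receptor outage windows.
#' @param z_ref receptor height, m; `gradient_z` gradient heights, m.
#' @param z0,h_c roughness length and canopy height, m.
#' @param field_size square field side, m; `receptor_inset` distance of the
#'   receptor from the downwind field edge, m.
#' @param seed RNG seed.
#' @return object of class `campaign_config`.
#' @export
campaign_config <- function(n_days = 22, dt_min = 30, application_day = 1,
                            dose_g_per_ha = 544, r0 = 0.18,
                            avail_truth = c(a1 = 57, k1 = 0.61,
                                            a2 = 43, k2 = 0.012),
                            ustar_night = 0.18, ustar_day = 0.55,
                            t_mean = 16, t_amp = 11,
                            wd_mean = 195, wd_sd = 25,
                            l_day = -67, l_night = 29,
                            conc_noise = 0.14, gradient_noise = 0.07,
                            c_bgd_mean = 5.7, c_bgd_sd = 2.2,
                            filter_cv = 0.10, ground_frac = 0.68,
                            outages = list(c(3, 4), c(11, 14)),
                            z_ref = 1.9, gradient_z = c(0.63, 1.23, 2.03),
                            z0 = 0.0035, h_c = 0.5,
                            field_size = 450, receptor_inset = 40,
                            seed = 1L) {
  if (n_days < 2) stop("n_days must be >= 2")
  if (dose_g_per_ha <= 0) stop("dose must be > 0")
  if (conc_noise < 0 || gradient_noise < 0) stop("noise must be >= 0")
  cfg <- as.list(environment())
  structure(cfg, class = "campaign_config")
}

#' @export
print.campaign_config <- function(x, ...) {
  cat(sprintf(
    "<campaign_config> %d days @ %d min, application day %g, dose %g g/ha\n",
    x$n_days, x$dt_min, x$application_day, x$dose_g_per_ha))
  cat(sprintf("  availability: r0 %.2f, %g e^-%gt + %g e^-%gt (%%)\n",
              x$r0, x$avail_truth["a1"], x$avail_truth["k1"],
              x$avail_truth["a2"], x$avail_truth["k2"]))
  invisible(x)
}

#' Default field geometry of a campaign
#'
#' One square field with the receptor `receptor_inset` metres inside its
#' downwind (north) edge, emitting at the configured dose.
#'
#' @param cfg a [campaign_config()].
#' @return list with `sources` (a [source_map()]) and `receptor` `c(x,y,z)`.
#' @export
default_sources <- function(cfg) {
  s <- cfg$field_size
  poly <- data.frame(
    x = c(-s / 2, s / 2, s / 2, -s / 2),
    y = c(cfg$receptor_inset - s, cfg$receptor_inset - s,
          cfg$receptor_inset, cfg$receptor_inset))
  list(sources = source_map(list(field_A = poly),
                            dose_g_per_ha = cfg$dose_g_per_ha),
       receptor = c(0, 0, cfg$z_ref))
}

#' Generate a diurnal 30-min met series
#'
#' Smooth solar-driven cycles: friction velocity between the configured
#' night and day values, a temperature sinusoid peaking mid-afternoon, the
#' Obukhov length cycling from unstable daytime to stable nighttime values,
#' normally distributed wind direction, and sigma_w proportional to u*.
#'
#' @param cfg a [campaign_config()].
#' @return met data.frame (see [validate_met()]) with `z0`, `d`, `h_c`
#'   columns and a `day` column (days since campaign start).
#' @export
generate_met <- function(cfg) {
  set.seed(cfg$seed)
  n <- cfg$n_days * 24 * 60 / cfg$dt_min
  t0 <- as.POSIXct("2018-04-16 00:00:00", tz = "UTC")
  ts <- t0 + seq(0, by = cfg$dt_min * 60, length.out = n)
  day <- as.numeric(difftime(ts, t0, units = "days"))
  hr <- (day %% 1) * 24
  solar <- pmax(0, sin(pi * (hr - 6) / 12))
  ustar <- cfg$ustar_night +
    (cfg$ustar_day - cfg$ustar_night) * solar * (1 + 0.1 * stats::rnorm(n))
  ustar <- pmin(pmax(ustar, cfg$ustar_night), cfg$ustar_day)
  inv_l <- (1 / cfg$l_night) * (1 - solar) + (1 / cfg$l_day) * solar
  inv_l <- inv_l * (1 + 0.15 * stats::rnorm(n))
  inv_l[abs(inv_l) < 1e-5] <- sign(inv_l[abs(inv_l) < 1e-5] + 1e-12) * 1e-5
  t_air <- cfg$t_mean + cfg$t_amp * cos(2 * pi * (hr - 14) / 24) +
    0.3 * stats::rnorm(n)
  met <- data.frame(
    timestamp = ts, day = day,
    ustar = ustar, obukhov_l = 1 / inv_l,
    wd = (cfg$wd_mean + cfg$wd_sd * stats::rnorm(n)) %% 360,
    sigma_w = 1.3 * ustar * (1 + 0.05 * stats::rnorm(n)),
    t_air = t_air,
    z0 = cfg$z0, h_c = cfg$h_c, d = 2 / 3 * cfg$h_c
  )
  validate_met(met, z_ref = cfg$z_ref)
  met
}

## availability ratio at t days after application (0 before application)
r_true_at <- function(cfg, day) {
  t_app <- day - cfg$application_day
  a <- cfg$avail_truth
  r <- cfg$r0 * (a["a1"] * exp(-a["k1"] * pmax(t_app, 0)) +
                   a["a2"] * exp(-a["k2"] * pmax(t_app, 0))) / 100
  unname(ifelse(t_app < 0, 0, r))
}

#' Generate the true volatilisation flux of a campaign
#'
#' The availability ratio follows the configured double exponential; the
#' surface concentration is \eqn{C(z_0) = r(t) p_{sat}(T) M/(RT) 10^9} and
#' the flux solves the coupled resistance + ambient-feedback balance
#' \eqn{F = (C(z_0) - C_{ref})/(R_a+R_b)} with \eqn{C_{ref} = DF + C_{bgd}},
#' i.e. \eqn{F = (C(z_0) - C_{bgd})/(R_a + R_b + D)} (the feedback is linear,
#' so the fixed point is solved exactly).
#'
#' @param cfg a [campaign_config()].
#' @param met met series from [generate_met()].
#' @param sources,receptor geometry; defaults from [default_sources()].
#' @return data.frame `timestamp, day, r_true, c_z0, d_coeff, flux, c_ref`
#'   (flux in ng m-2 s-1, emission positive).
#' @export
generate_truth_flux <- function(cfg, met, sources = NULL, receptor = NULL) {
  if (is.null(sources)) {
    geom <- default_sources(cfg)
    sources <- geom$sources; receptor <- geom$receptor
  }
  r_t <- r_true_at(cfg, met$day)
  c_z0 <- conc_from_vapour_pressure(r_t * saturation_pressure(met$t_air),
                                    met$t_air)
  r_a <- aerodynamic_resistance(cfg$z_ref, met$ustar, met$obukhov_l,
                                met$z0, met$d)
  r_b <- boundary_layer_resistance(met$ustar)
  disp <- dispersion_series(met, sources, receptor)
  flux <- pmax((c_z0 - cfg$c_bgd_mean) / (r_a + r_b + disp$d_coeff), 0)
  data.frame(timestamp = met$timestamp, day = met$day, r_true = r_t,
             c_z0 = c_z0, d_coeff = disp$d_coeff, flux = flux,
             c_ref = disp$d_coeff * flux + cfg$c_bgd_mean)
}

#' Generate noisy observations from a campaign truth
#'
#' Receptor concentrations \eqn{C = DF + C_{bgd}} with multiplicative noise
#' and outage blanking; gradient-level samples from the similarity profile
#' with their own noise (first three post-application days); and top/ground
#' filter-dose observations.
#'
#' @param cfg a [campaign_config()].
#' @param met met series.
#' @param truth output of [generate_truth_flux()].
#' @return list with `conc` (data.frame `timestamp, day, conc, rel_unc`),
#'   `c_bgd` (mean/sd actually realised pre-application), `gradient`
#'   (long data.frame `timestamp, day, z, conc`), `filters_top`,
#'   `filters_ground` (content_ng per pooled filter pair).
#' @export
generate_observations <- function(cfg, met, truth) {
  set.seed(cfg$seed + 1L)
  n <- nrow(met)
  bgd <- pmax(cfg$c_bgd_mean + cfg$c_bgd_sd * stats::rnorm(n), 0)
  conc <- truth$d_coeff * truth$flux + bgd
  conc <- conc * (1 + cfg$conc_noise * stats::rnorm(n))
  conc <- pmax(conc, 0)
  out_idx <- rep(FALSE, n)
  for (w in cfg$outages)
    out_idx <- out_idx | (met$day >= w[1] & met$day < w[2])
  conc[out_idx] <- NA
  ## gradient profile at the sampling heights over the first 3 days after
  ## application, built on the same similarity profile the gradient method
  ## assumes
  gwin <- met$day >= cfg$application_day & met$day < cfg$application_day + 3
  gi <- which(gwin)
  grad <- do.call(rbind, lapply(gi, function(i) {
    x_ref <- log(cfg$z_ref - met$d[i]) -
      psi_h((cfg$z_ref - met$d[i]) / met$obukhov_l[i])
    xz <- log(cfg$gradient_z - met$d[i]) -
      psi_h((cfg$gradient_z - met$d[i]) / met$obukhov_l[i])
    c_prof <- truth$c_ref[i] -
      truth$flux[i] / (VON_KARMAN * met$ustar[i]) * (xz - x_ref)
    data.frame(timestamp = met$timestamp[i], day = met$day[i],
               z = cfg$gradient_z,
               conc = pmax(c_prof *
                             (1 + cfg$gradient_noise * stats::rnorm(3)), 0))
  }))
  ## filter doses: 9 pooled pairs above the canopy, 9 at the ground
  area_pair <- 2 * pi * (0.09 / 2)^2
  top <- stats::rnorm(9, cfg$dose_g_per_ha,
                      cfg$filter_cv * cfg$dose_g_per_ha)
  grd <- stats::rnorm(9, cfg$ground_frac * cfg$dose_g_per_ha,
                      cfg$filter_cv * cfg$ground_frac * cfg$dose_g_per_ha)
  list(
    conc = data.frame(timestamp = met$timestamp, day = met$day,
                      conc = conc, rel_unc = cfg$conc_noise),
    c_bgd = list(mean = mean(bgd[met$day < cfg$application_day]),
                 sd = stats::sd(bgd[met$day < cfg$application_day])),
    gradient = grad,
    filters_top = g_ha_to_ng_m2(top) * area_pair,
    filters_ground = g_ha_to_ng_m2(grd) * area_pair
  )
}

#' Simulate a complete campaign
#'
#' Runs [generate_met()], [generate_truth_flux()] and
#' [generate_observations()] with the default geometry.
#'
#' @param cfg a [campaign_config()].
#' @return list `config, met, sources, receptor, truth, obs`.
#' @export
simulate_campaign <- function(cfg = campaign_config()) {
  geom <- default_sources(cfg)
  met <- generate_met(cfg)
  truth <- generate_truth_flux(cfg, met, geom$sources, geom$receptor)
  obs <- generate_observations(cfg, met, truth)
  list(config = cfg, met = met, sources = geom$sources,
       receptor = geom$receptor, truth = truth, obs = obs)
}
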