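## Monte-Carlo propagation of input and parameter uncertainty through the
## dispersion + inversion chain to per-step flux percentile bands and
## cumulative-loss bounds. All parameters are sampled independently;
## percentage standard deviations act multiplicatively.

#' Monte-Carlo parameter specification
#'
#' Distributional assumptions for the inversion inputs: log-normal roughness
#' length (arithmetic mean/sd converted internally to log-space), normal
#' displacement height, sensor position, background concentration, and
#' multiplicative percentage errors on friction velocity, Obukhov length,
#' lateral wind standard deviation and concentration; wind direction gets an
#' additive normal error in degrees.
#'
#' @param z0_mean,z0_sd roughness length arithmetic mean and sd, m.
#' @param d_sd displacement-height sd, m (mean is 2/3 of canopy height).
#' @param sensor_sd length-3 sd of the receptor x, y, z position, m.
#' @param ustar_pct,obukhov_pct,sigma_w_pct,conc_pct fractional (1-sigma)
#'   errors applied multiplicatively.
#' @param wd_sd wind-direction sd, degrees.
#' @param c_bgd_mean,c_bgd_sd background concentration, ng m-3.
#' @param n_draws number of Monte-Carlo draws (>= 2).
#' @return object of class `mc_spec`.
#' @export
mc_spec <- function(z0_mean = 0.0035, z0_sd = 0.0004, d_sd = 0.03,
                    sensor_sd = c(1, 1, 0.1),
                    ustar_pct = 0.14, obukhov_pct = 0.40,
                    sigma_w_pct = 0.14, conc_pct = 0.14, wd_sd = 12.5,
                    c_bgd_mean = 5.7, c_bgd_sd = 2.2, n_draws = 100) {
  sds <- c(z0_sd, d_sd, sensor_sd, ustar_pct, obukhov_pct, sigma_w_pct,
           conc_pct, wd_sd, c_bgd_sd)
  if (any(sds < 0)) stop("standard deviations must be >= 0")
  if (n_draws < 2) stop("n_draws must be >= 2")
  structure(list(z0_mean = z0_mean, z0_sd = z0_sd, d_sd = d_sd,
                 sensor_sd = sensor_sd, ustar_pct = ustar_pct,
                 obukhov_pct = obukhov_pct, sigma_w_pct = sigma_w_pct,
                 conc_pct = conc_pct, wd_sd = wd_sd,
                 c_bgd_mean = c_bgd_mean, c_bgd_sd = c_bgd_sd,
                 n_draws = n_draws),
            class = "mc_spec")
}

#' @export
print.mc_spec <- function(x, ...) {
  cat("<mc_spec>", x$n_draws, "draws; z0 ~ logN(", x$z0_mean, ",",
      x$z0_sd, "); u* +/-", 100 * x$ustar_pct, "%; L +/-",
      100 * x$obukhov_pct, "%; wd sd", x$wd_sd, "deg; C +/-",
      100 * x$conc_pct, "%; C_bgd ~ N(", x$c_bgd_mean, ",", x$c_bgd_sd,
      ")\n")
  invisible(x)
}

#' Read a Monte-Carlo parameter spec from a YAML file
#'
#' Keys mirror the [mc_spec()] arguments (`z0: {mean, sd}`,
#' `ustar: {pct}`, `wd: {sd}`, `c_bgd: {mean, sd}`, `sensor: {sd}`,
#' `n_draws`); missing keys keep their defaults.
#'
#' @param path YAML file.
#' @return an [mc_spec()].
#' @export
read_mc_spec <- function(path) {
  y <- yaml::read_yaml(path)
  g <- function(k, f, def) if (!is.null(y[[k]][[f]])) y[[k]][[f]] else def
  mc_spec(
    z0_mean = g("z0", "mean", 0.0035), z0_sd = g("z0", "sd", 0.0004),
    d_sd = g("d", "sd", 0.03),
    sensor_sd = unlist(g("sensor", "sd", c(1, 1, 0.1))),
    ustar_pct = g("ustar", "pct", 0.14),
    obukhov_pct = g("obukhov_l", "pct", 0.40),
    sigma_w_pct = g("sigma_w", "pct", 0.14),
    conc_pct = g("conc", "pct", 0.14), wd_sd = g("wd", "sd", 12.5),
    c_bgd_mean = g("c_bgd", "mean", 5.7), c_bgd_sd = g("c_bgd", "sd", 2.2),
    n_draws = if (!is.null(y$n_draws)) y$n_draws else 100)
}

## arithmetic mean/sd -> log-space parameters of a log-normal
lognormal_params <- function(mean, sd) {
  sdlog2 <- log(1 + (sd / mean)^2)
  list(meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

## draw a multiplicative factor 1 + pct*N, redrawn while <= floor so the
## perturbed physical quantity keeps its sign/validity
mult_factor <- function(n, pct, floor = 0.05) {
  f <- 1 + pct * stats::rnorm(n)
  bad <- which(f <= floor)
  redraws <- 0L
  while (length(bad)) {
    f[bad] <- 1 + pct * stats::rnorm(length(bad))
    redraws <- redraws + length(bad)
    bad <- bad[f[bad] <= floor]
  }
  attr(f, "redraws") <- redraws
  f
}

#' Draw one perturbed parameter set
#'
#' @param spec an [mc_spec()].
#' @param n number of independent draws per parameter.
#' @param h_c canopy height, m, used for the displacement-height mean.
#' @return list of vectors: `z0`, `d`, `dx`, `dy`, `dz` (sensor offsets),
#'   `f_ustar`, `f_l`, `f_sigma_w`, `f_conc` (multiplicative factors),
#'   `wd_err` (deg), `c_bgd`. Invalid draws (non-positive roughness or
#'   friction velocity) are redrawn; the redraw count is attached as an
#'   attribute.
#' @export
sample_parameters <- function(spec, n = 1, h_c = 0.5) {
  lp <- lognormal_params(spec$z0_mean, max(spec$z0_sd, 1e-12))
  z0 <- if (spec$z0_sd > 0) stats::rlnorm(n, lp$meanlog, lp$sdlog)
  else rep(spec$z0_mean, n)
  d <- stats::rnorm(n, 2 / 3 * h_c, spec$d_sd)
  d <- pmax(d, 0)
  f_ustar <- mult_factor(n, spec$ustar_pct)
  f_l <- mult_factor(n, spec$obukhov_pct)
  f_sigma_w <- mult_factor(n, spec$sigma_w_pct)
  f_conc <- 1 + spec$conc_pct * stats::rnorm(n)
  out <- list(
    z0 = z0, d = d,
    dx = stats::rnorm(n, 0, spec$sensor_sd[1]),
    dy = stats::rnorm(n, 0, spec$sensor_sd[2]),
    dz = stats::rnorm(n, 0, spec$sensor_sd[3]),
    f_ustar = f_ustar, f_l = f_l, f_sigma_w = f_sigma_w, f_conc = f_conc,
    wd_err = stats::rnorm(n, 0, spec$wd_sd),
    c_bgd = stats::rnorm(n, spec$c_bgd_mean, spec$c_bgd_sd)
  )
  attr(out, "redraws") <- sum(attr(f_ustar, "redraws"),
                              attr(f_l, "redraws"),
                              attr(f_sigma_w, "redraws"))
  out
}

#' Monte-Carlo flux with percentile bands
#'
#' Re-runs the dispersion + inversion chain `n_draws` times with perturbed
#' inputs and reports per-step empirical percentiles of the flux. In
#' `"step"` mode each 30-min step gets independent parameter draws (one
#' parameter set per time step); in `"trajectory"` mode each draw uses one
#' parameter set for the whole campaign, which preserves temporal
#' correlation of the error and is the mode used for cumulative-loss
#' bounds.
#'
#' @param met validated met data.frame (with `z0`, `d`, `h_c` columns or
#'   defaults).
#' @param conc receptor concentration per step, ng m-3.
#' @param sources a [source_map()].
#' @param receptor numeric `c(x, y, z)`.
#' @param spec an [mc_spec()].
#' @param mode `"step"` or `"trajectory"`.
#' @param d_floor minimum usable dispersion coefficient, s m-1.
#' @param probs percentiles reported per step.
#' @return list with `summary` (data.frame `timestamp`, `flux` = median,
#'   `p05`, `p95`, `n_mc`, `frac_masked`) and `draws` (steps x draws flux
#'   matrix, NA where masked). Steps with more than 50 percent masked draws
#'   have NA bands.
#' @export
mc_flux <- function(met, conc, sources, receptor, spec = mc_spec(),
                    mode = c("step", "trajectory"), d_floor = 1e-3,
                    probs = c(0.05, 0.5, 0.95)) {
  mode <- match.arg(mode)
  n <- nrow(met)
  nd <- spec$n_draws
  h_c <- if (!is.null(met$h_c)) met$h_c[1] else 0.5
  draws <- matrix(NA_real_, n, nd)
  for (j in seq_len(nd)) {
    pj <- sample_parameters(spec, n = if (mode == "step") n else 1,
                            h_c = h_c)
    idx <- if (mode == "step") seq_len(n) else rep(1L, n)
    rec <- receptor   # sensor offsets enter the geometry, not the conc
    ustar_j <- met$ustar * pj$f_ustar[idx]
    l_j <- met$obukhov_l * pj$f_l[idx]
    wd_j <- (met$wd + pj$wd_err[idx]) %% 360
    sw_j <- met$sigma_w * pj$f_sigma_w[idx]
    conc_j <- conc * pj$f_conc[idx]
    cbgd_j <- pj$c_bgd[idx]
    dco <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      if (is.na(ustar_j[i]) || is.na(l_j[i]) || is.na(wd_j[i]) ||
          is.na(conc[i])) next
      k <- idx[i]
      rj <- c(rec[1] + pj$dx[k], rec[2] + pj$dy[k],
              max(rec[3] + pj$dz[k], pj$d[k] + pj$z0[k] + 0.05))
      dco[i] <- polygon_dispersion(rj, sources, ustar_j[i], l_j[i],
                                   wd_j[i], pj$z0[k], pj$d[k],
                                   sigma_w = sw_j[i])$d_coeff
    }
    ok <- !is.na(dco) & dco > d_floor
    draws[ok, j] <- (conc_j[ok] - cbgd_j[ok]) / dco[ok]
  }
  frac_masked <- rowMeans(is.na(draws))
  qs <- t(apply(draws, 1, function(x) {
    if (mean(is.na(x)) > 0.5) return(rep(NA_real_, length(probs)))
    stats::quantile(x, probs, na.rm = TRUE)
  }))
  summary <- data.frame(timestamp = met$timestamp,
                        flux = qs[, 2], p05 = qs[, 1], p95 = qs[, 3],
                        n_mc = nd, frac_masked = frac_masked,
                        method = "inversion")
  list(summary = summary, draws = draws)
}

#' Monte-Carlo cumulative volatilised fraction of the dose
#'
#' Applies gap-filling and trapezoidal cumulation to every draw of a
#' trajectory-mode [mc_flux()] run and takes percentiles over the cumulative
#' trajectories (not over per-step bands).
#'
#' @param draws steps x draws flux matrix (ng m-2 s-1, NA where masked).
#' @param timestamp POSIXct grid matching the rows of `draws`.
#' @param modelled modelled flux on the same grid, used to fill masked steps
#'   per draw (see [gapfill_flux()]); `NULL` integrates masked steps as 0.
#' @param dose_g_per_ha applied dose.
#' @param window_days gap-filling window.
#' @param probs percentiles of the cumulative trajectories.
#' @return list with `final` (named vector: mean, p05, p95 of the final
#'   cumulative percent) and `series` (data.frame of the mean and percentile
#'   cumulative trajectories).
#' @export
mc_cumulative <- function(draws, timestamp, modelled = NULL,
                          dose_g_per_ha = 544, window_days = 7,
                          probs = c(0.05, 0.95)) {
  nd <- ncol(draws)
  cum <- matrix(NA_real_, nrow(draws), nd)
  for (j in seq_len(nd)) {
    fj <- draws[, j]
    if (!is.null(modelled) && any(is.na(fj))) {
      fj <- tryCatch(
        gapfill_flux(timestamp, fj, modelled, window_days)$flux,
        error = function(e) fj)
    }
    cum[, j] <- cumulate_flux(timestamp, fj, dose_g_per_ha)$cum_pct
  }
  qs <- t(apply(cum, 1, stats::quantile, probs = probs, na.rm = TRUE))
  mean_tr <- rowMeans(cum, na.rm = TRUE)
  final <- c(mean = unname(mean_tr[nrow(cum)]),
             p05 = unname(qs[nrow(cum), 1]),
             p95 = unname(qs[nrow(cum), 2]))
  list(final = final,
       series = data.frame(timestamp = timestamp, mean = mean_tr,
                           p05 = qs[, 1], p95 = qs[, 2]))
}
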