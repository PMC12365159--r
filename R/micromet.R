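## von Karman constant
VON_KARMAN <- 0.4

#' Integrated Monin-Obukhov stability correction for scalars
#'
#' Computes the integrated stability correction \eqn{\Psi_H(\zeta)} used in the
#' log-profile resistance and aerodynamic-gradient formulations, with the
#' Businger-Dyer form \eqn{\Psi_H = 2\log((1+x^2)/2)}, \eqn{x=(1-\gamma\zeta)^{1/4}}
#' on the unstable side and a linear form \eqn{\Psi_H = -\beta\zeta} on the
#' stable side.
#'
#' @param zeta dimensionless stability parameter \eqn{(z-d)/L}; vectorised.
#' @param gamma_u unstable-side coefficient (default 16).
#' @param beta_s stable-side coefficient (default 5.2).
#' @param clamp length-2 numeric; `zeta` is clamped to this interval before
#'   evaluation to avoid pathological values in calm periods
#'   (default `c(-5, 2)`).
#' @return numeric vector; 0 at neutrality, positive (resistance-reducing) for
#'   unstable, negative for stable conditions.
#' @export
#' @examples
#' psi_h(0)
#' psi_h(c(-1, 0.5))
psi_h <- function(zeta, gamma_u = 16, beta_s = 5.2, clamp = c(-5, 2)) {
  stopifnot(is.numeric(zeta))
  z <- pmin(pmax(zeta, clamp[1]), clamp[2])
  out <- numeric(length(z))
  un <- !is.na(z) & z < 0
  if (any(un)) {
    x <- (1 - gamma_u * z[un])^0.25
    out[un] <- 2 * log((1 + x^2) / 2)
  }
  st <- !is.na(z) & z >= 0
  out[st] <- -beta_s * z[st]
  out[is.na(z)] <- NA_real_
  out
}

#' Integrated stability correction for momentum
#'
#' Businger-Dyer \eqn{\Psi_M} (unstable) and linear stable form, used when
#' matching the power-law wind profile to the Monin-Obukhov profile.
#'
#' @inheritParams psi_h
#' @return numeric vector.
#' @export
psi_m <- function(zeta, gamma_u = 16, beta_s = 5.2, clamp = c(-5, 2)) {
  stopifnot(is.numeric(zeta))
  z <- pmin(pmax(zeta, clamp[1]), clamp[2])
  out <- numeric(length(z))
  un <- !is.na(z) & z < 0
  if (any(un)) {
    x <- (1 - gamma_u * z[un])^0.25
    out[un] <- 2 * log((1 + x) / 2) + log((1 + x^2) / 2) - 2 * atan(x) + pi / 2
  }
  st <- !is.na(z) & z >= 0
  out[st] <- -beta_s * z[st]
  out[is.na(z)] <- NA_real_
  out
}

#' Dimensionless scalar-gradient function phi_H
#'
#' @inheritParams psi_h
#' @return numeric vector; 1 at neutrality.
#' @export
phi_h <- function(zeta, gamma_u = 16, beta_s = 5.2, clamp = c(-5, 2)) {
  z <- pmin(pmax(zeta, clamp[1]), clamp[2])
  ifelse(z < 0, (1 - gamma_u * z)^(-0.5), 1 + beta_s * z)
}

#' Aerodynamic resistance between the canopy and a reference height
#'
#' \eqn{R_a(z_{ref}) = (\log((z_{ref}-d)/z_0) - \Psi_H)/(k u_*)}.
#'
#' @param z_ref reference (measurement) height, m above ground.
#' @param ustar friction velocity, m s-1 (> 0); vectorised.
#' @param obukhov_l Obukhov length, m (neutral as large |L|); vectorised.
#' @param z0 roughness length, m.
#' @param d displacement height, m; must satisfy `z_ref > d + z0`.
#' @param ... passed to [psi_h()] (stability-form coefficients, clamp).
#' @return aerodynamic resistance, s m-1.
#' @export
#' @examples
#' aerodynamic_resistance(1.9, ustar = 0.3, obukhov_l = 1e6,
#'                        z0 = 0.0035, d = 0.33)
aerodynamic_resistance <- function(z_ref, ustar, obukhov_l, z0, d = 0, ...) {
  if (any(z_ref <= d + z0, na.rm = TRUE))
    stop("z_ref must exceed d + z0 (geometry misconfiguration)")
  if (any(ustar <= 0, na.rm = TRUE)) stop("ustar must be > 0")
  zeta <- (z_ref - d) / obukhov_l
  (log((z_ref - d) / z0) - psi_h(zeta, ...)) / (VON_KARMAN * ustar)
}

#' Quasi-laminar boundary-layer resistance
#'
#' \eqn{R_b = 2/(k u_*) (Sc/Pr)^{2/3}}.
#'
#' @param ustar friction velocity, m s-1 (> 0).
#' @param schmidt Schmidt number of the transported compound; default the
#'   chlorothalonil estimate of [schmidt_number()].
#' @param prandtl Prandtl number of air (default 0.72).
#' @return resistance, s m-1; proportional to 1/ustar.
#' @export
boundary_layer_resistance <- function(ustar, schmidt = schmidt_number(),
                                      prandtl = 0.72) {
  stopifnot(all(ustar > 0, na.rm = TRUE), schmidt > 0, prandtl > 0)
  2 / (VON_KARMAN * ustar) * (schmidt / prandtl)^(2 / 3)
}

#' Schmidt number from a Graham's-law diffusivity estimate
#'
#' No measured molecular diffusivity exists for chlorothalonil, so its
#' diffusivity in air is estimated from the water-vapour diffusivity scaled by
#' \eqn{\sqrt{M_{H2O}/M}} (Graham's law), and \eqn{Sc = \nu/D}.
#'
#' @param molar_mass compound molar mass, g mol-1 (default chlorothalonil,
#'   265.911).
#' @param d_h2o water-vapour diffusivity in air, m2 s-1 (default 2.4e-5 at
#'   ~20 degC).
#' @param nu_air kinematic viscosity of air, m2 s-1 (default 1.5e-5).
#' @return dimensionless Schmidt number.
#' @export
schmidt_number <- function(molar_mass = 265.911, d_h2o = 2.4e-5,
                           nu_air = 1.5e-5) {
  d_chem <- d_h2o * sqrt(18.015 / molar_mass)
  nu_air / d_chem
}

#' Validate a 30-min micrometeorological record table
#'
#' Checks the invariants assumed downstream: positive `ustar` and `z0`,
#' wind direction in [0, 360), non-zero Obukhov length, displacement height
#' below the measurement height.
#'
#' @param met data.frame with columns `timestamp`, `ustar`, `obukhov_l`,
#'   `wd`, `sigma_w`, `t_air`, and optionally `z0`, `d`, `h_c`.
#' @param z_ref measurement height used against `d`, m (default 1.9).
#' @return `met`, invisibly, if valid; otherwise an error.
#' @export
validate_met <- function(met, z_ref = 1.9) {
  need <- c("timestamp", "ustar", "obukhov_l", "wd", "sigma_w", "t_air")
  miss <- setdiff(need, names(met))
  if (length(miss))
    stop("met is missing columns: ", paste(miss, collapse = ", "))
  ok <- stats::complete.cases(met[, c("ustar", "obukhov_l", "wd")])
  if (any(met$ustar[ok] <= 0)) stop("ustar must be > 0")
  if (any(met$obukhov_l[ok] == 0)) stop("obukhov_l must be non-zero")
  if (any(met$wd[ok] < 0 | met$wd[ok] >= 360)) stop("wd must be in [0, 360)")
  if (!is.null(met$z0) && any(met$z0 <= 0, na.rm = TRUE)) stop("z0 must be > 0")
  if (!is.null(met$d) && any(met$d >= z_ref, na.rm = TRUE))
    stop("displacement height must be below the measurement height")
  invisible(met)
}

#' Read a 30-min met CSV
#'
#' Expects ISO-8601 timestamps and named columns `ustar`, `obukhov_l`,
#' `wd_deg`, `sigma_w`, `t_air_c`; gaps encoded as empty fields. Canopy
#' geometry (`z0`, canopy height `h_c`) may be supplied as columns or as
#' arguments; the displacement height defaults to 2/3 of the canopy height.
#'
#' @param path CSV file path.
#' @param z0 roughness length, m, if not a column.
#' @param h_c canopy height, m, if not a column.
#' @return validated data.frame with standard column names.
#' @export
read_met_csv <- function(path, z0 = 0.0035, h_c = 0.5) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  met <- data.frame(
    timestamp = as.POSIXct(raw$timestamp, tz = "UTC"),
    ustar = raw$ustar,
    obukhov_l = raw$obukhov_l,
    wd = raw$wd_deg,
    sigma_w = raw$sigma_w,
    t_air = raw$t_air_c
  )
  met$z0 <- if (!is.null(raw$z0)) raw$z0 else z0
  met$h_c <- if (!is.null(raw$h_c)) raw$h_c else h_c
  met$d <- if (!is.null(raw$d)) raw$d else 2 / 3 * met$h_c
  validate_met(met)
  met
}
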