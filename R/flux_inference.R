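## Flux retrieval: inversion of the forward dispersion relation
## C = D * F + C_bgd, and the aerodynamic-gradient method F = -u* C*.
## Sign convention throughout: emission positive, deposition negative.

#' Invert concentrations to volatilisation fluxes
#'
#' Algebraic inversion `F = (C - C_bgd) / D` per 30-min step. Steps whose
#' dispersion coefficient falls below `d_floor` are masked (`NA`), not
#' zero-filled: the inversion variance explodes as 1/D in calm periods or
#' wrong wind sectors.
#'
#' @param conc receptor concentration, ng m-3; vector aligned with `d_coeff`.
#' @param d_coeff dispersion coefficient per step, s m-1.
#' @param c_bgd background concentration, ng m-3 (scalar or vector).
#' @param timestamp optional timestamps carried into the output.
#' @param d_floor minimum usable D, s m-1 (default 1e-3).
#' @return data.frame `timestamp` (if given), `flux` (ng m-2 s-1), `d_coeff`,
#'   `method`. Attribute `sign_convention` states that emission is positive.
#' @export
invert_flux <- function(conc, d_coeff, c_bgd, timestamp = NULL,
                        d_floor = 1e-3) {
  if (length(conc) != length(d_coeff))
    stop("conc and d_coeff must have matching timestamps/length")
  usable <- !is.na(d_coeff) & d_coeff > d_floor
  flux <- rep(NA_real_, length(conc))
  flux[usable] <- (conc[usable] - rep_len(c_bgd, length(conc))[usable]) /
    d_coeff[usable]
  out <- data.frame(flux = flux, d_coeff = d_coeff,
                    method = ifelse(usable & !is.na(flux),
                                    "inversion", "masked"))
  if (!is.null(timestamp)) out <- cbind(timestamp = timestamp, out)
  attr(out, "sign_convention") <- "emission positive, deposition negative"
  out
}

#' Aerodynamic-gradient flux from a multi-height concentration profile
#'
#' Fits the similarity profile by ordinary least squares of concentration
#' against \eqn{\ln(z-d) - \Psi_H((z-d)/L)}; the scaling concentration is
#' \eqn{C_* = k \, \partial C/\partial(\ln(z-d)-\Psi_H)} and the flux
#' \eqn{F = -u_* C_*}.
#'
#' @param z measurement heights, m above ground (>= 2 valid levels above `d`).
#' @param conc concentrations at `z`, ng m-3 (NA allowed).
#' @param ustar friction velocity, m s-1.
#' @param obukhov_l Obukhov length, m.
#' @param d displacement height, m.
#' @param ... stability options passed to [psi_h()].
#' @return flux, ng m-2 s-1 (emission positive).
#' @export
#' @examples
#' z <- c(0.63, 1.23, 2.03)
#' prof <- 100 - 5 * (log(z - 0.33))   # decreasing with height: emission
#' gradient_flux(z, prof, ustar = 0.3, obukhov_l = 1e6, d = 0.33)
gradient_flux <- function(z, conc, ustar, obukhov_l, d = 0, ...) {
  ok <- !is.na(conc) & !is.na(z) & z > d
  if (sum(ok) < 2) stop("gradient_flux needs at least 2 valid levels above d")
  xv <- log(z[ok] - d) - psi_h((z[ok] - d) / obukhov_l, ...)
  slope <- stats::cov(xv, conc[ok]) / stats::var(xv)
  c_star <- VON_KARMAN * slope
  -ustar * c_star
}

#' Per-source contribution of polygon sources to the receptor concentration
#'
#' Runs the dispersion model per step and reports the fraction of the
#' modelled concentration attributable to each source (weighted by its
#' relative emission strength), plus campaign means.
#'
#' @inheritParams dispersion_series
#' @return list with `steps` (data.frame of per-step fractions) and
#'   `campaign_mean` (named vector).
#' @export
attribute_sources <- function(met, sources, receptor, ...) {
  ds <- dispersion_series(met, sources, receptor, ...)
  cols <- grep("^contrib_", names(ds), value = TRUE)
  cm <- colMeans(ds[, cols, drop = FALSE], na.rm = TRUE)
  names(cm) <- sub("^contrib_", "", names(cm))
  list(steps = ds[, c("timestamp", cols)], campaign_mean = cm)
}

#' Write a flux series CSV
#'
#' Columns `timestamp, flux_ng_m2_s, p05, p95, method, d_coeff, n_mc`; a
#' header comment records the sign convention (emission positive).
#'
#' @param flux data.frame with at least `timestamp` and `flux`; optional
#'   `p05`, `p95`, `method`, `d_coeff`, `n_mc`.
#' @param path output file.
#' @param extra_header optional additional `# key: value` comment lines.
#' @export
write_flux_csv <- function(flux, path, extra_header = character()) {
  out <- data.frame(
    timestamp = format(flux$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    flux_ng_m2_s = flux$flux,
    p05 = if (!is.null(flux$p05)) flux$p05 else NA,
    p95 = if (!is.null(flux$p95)) flux$p95 else NA,
    method = if (!is.null(flux$method)) flux$method else "inversion",
    d_coeff = if (!is.null(flux$d_coeff)) flux$d_coeff else NA,
    n_mc = if (!is.null(flux$n_mc)) flux$n_mc else NA
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# sign convention: emission positive, deposition negative",
               extra_header), con)
  utils::write.csv(out, con, row.names = FALSE)
}
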