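## PTR-TOF quantification utilities: chlorine isotope envelopes, summed peak
## counts, zero-intercept calibration, sensitivity conversion and limits of
## detection.

## exact masses (Da) and natural abundances of the isotopes used here
ISOTOPES <- list(
  C  = list(mass = c(12, 13.003355), ab = c(0.9893, 0.0107)),
  H  = list(mass = c(1.007825, 2.014102), ab = c(0.999885, 0.000115)),
  N  = list(mass = c(14.003074, 15.000109), ab = c(0.99636, 0.00364)),
  O  = list(mass = c(15.994915, 16.999132, 17.999160),
            ab = c(0.99757, 0.00038, 0.00205)),
  Cl = list(mass = c(34.968853, 36.965903), ab = c(0.7577, 0.2423))
)
PROTON_MASS <- 1.007276

## convolve two (mass, ab) distributions, pruning tiny terms
convolve_iso <- function(a, b, prune = 1e-10) {
  m <- outer(a$mass, b$mass, "+")
  p <- outer(a$ab, b$ab)
  o <- order(m)
  m <- m[o]; p <- p[o]
  ## merge numerically identical masses
  grp <- cumsum(c(TRUE, diff(m) > 1e-6))
  m <- as.numeric(tapply(m * p, grp, sum) / tapply(p, grp, sum))
  p <- as.numeric(tapply(p, grp, sum))
  keep <- p > prune
  list(mass = m[keep], ab = p[keep])
}

element_distribution <- function(el, count) {
  iso <- ISOTOPES[[el]]
  if (is.null(iso)) stop("unknown element: ", el)
  out <- list(mass = 0, ab = 1)
  for (i in seq_len(count)) out <- convolve_iso(out, iso)
  out
}

#' Isotopologue envelope of a protonated (and optionally hydrated) ion
#'
#' Convolves the natural isotope distributions of the elements in a formula
#' (dominated by 35Cl/37Cl for polychlorinated species), adds the adduct
#' mass, clusters isotopologues into nominal-mass peaks and flags the
#' significant ones. With the default 20 percent-of-base-peak threshold the
#' Cl4 envelope has exactly three significant peaks (M, M+2, M+4; the M+6
#' isotopologue sits near 10 percent of the base peak and is excluded).
#'
#' @param formula named integer vector of element counts, e.g.
#'   `c(C = 8, Cl = 4, N = 2)` for chlorothalonil.
#' @param adduct `"H"` (protonated) or `"H.H2O"` (protonated water cluster).
#' @param threshold significance threshold as a fraction of the base peak
#'   (default 0.2).
#' @return object of class `isotope_envelope`: data.frame `mz` (exact m/z),
#'   `nominal` (rounded), `abundance` (normalised to sum 1), `significant`;
#'   attributes `species`, `threshold`.
#' @export
#' @examples
#' env <- isotope_envelope(c(C = 8, Cl = 4, N = 2), adduct = "H")
#' sum(env$significant)   # 3 significant Cl4 peaks
isotope_envelope <- function(formula, adduct = c("H", "H.H2O"),
                             threshold = 0.2) {
  adduct <- match.arg(adduct)
  if (is.null(names(formula)) || any(!names(formula) %in% names(ISOTOPES)))
    stop("formula must be a named vector over elements ",
         paste(names(ISOTOPES), collapse = ", "))
  dist <- list(mass = 0, ab = 1)
  for (el in names(formula))
    dist <- convolve_iso(dist, element_distribution(el, formula[[el]]))
  mz <- dist$mass + PROTON_MASS
  if (adduct == "H.H2O") {
    h2o <- convolve_iso(element_distribution("H", 2),
                        element_distribution("O", 1))
    dist <- convolve_iso(dist, h2o)
    mz <- dist$mass + PROTON_MASS
  }
  ## cluster isobars into nominal-mass peaks (weighted-mean exact mass)
  nom <- round(mz)
  ab <- as.numeric(tapply(dist$ab, nom, sum))
  mzc <- as.numeric(tapply(mz * dist$ab, nom, sum)) / ab
  o <- order(mzc)
  mzc <- mzc[o]; ab <- ab[o]
  ab <- ab / sum(ab)
  out <- data.frame(mz = mzc, nominal = round(mzc), abundance = ab,
                    significant = ab >= threshold * max(ab))
  structure(out,
            species = if (adduct == "H") "protonated" else "protonated+H2O",
            threshold = threshold, class = c("isotope_envelope",
                                             "data.frame"))
}

#' Sum spectrum counts over the significant peaks of one or more envelopes
#'
#' Sums counts within `tolerance` m/z of every significant peak; with the
#' default chlorothalonil envelopes (protonated + mono-hydrated) this is the
#' 6-peak sum used for quantification. Overlapping windows are collapsed
#' with a warning.
#'
#' @param mz,cps spectrum as paired vectors (counts per second per m/z bin).
#' @param envelopes a single [isotope_envelope()] or a list of them.
#' @param tolerance half-width of each m/z window (default 0.3).
#' @return total counts per second over all windows.
#' @export
sum_peaks <- function(mz, cps, envelopes, tolerance = 0.3) {
  if (inherits(envelopes, "isotope_envelope")) envelopes <- list(envelopes)
  centres <- sort(unlist(lapply(envelopes, function(e) e$mz[e$significant])))
  if (!length(centres)) return(0)
  lo <- centres - tolerance; hi <- centres + tolerance
  ## collapse overlapping windows
  keep_lo <- lo[1]; keep_hi <- hi[1]
  n_overlap <- 0L
  for (i in seq_along(centres)[-1]) {
    if (lo[i] <= keep_hi[length(keep_hi)]) {
      n_overlap <- n_overlap + 1L
      keep_hi[length(keep_hi)] <- max(keep_hi[length(keep_hi)], hi[i])
    } else {
      keep_lo <- c(keep_lo, lo[i]); keep_hi <- c(keep_hi, hi[i])
    }
  }
  if (n_overlap > 0)
    warning(n_overlap, " overlapping m/z window(s) collapsed")
  total <- 0
  for (i in seq_along(keep_lo))
    total <- total + sum(cps[mz >= keep_lo[i] & mz <= keep_hi[i]],
                         na.rm = TRUE)
  total
}

#' Zero-intercept calibration of instrument counts against a reference
#'
#' Least-squares slope through the origin of reference concentrations
#' against instrument counts, with a relative slope uncertainty from a
#' nonparametric bootstrap (default) or from the half-range of
#' leave-one-out slopes, for parity with scatter-based reporting.
#'
#' @param cps instrument response (counts per second).
#' @param reference co-located reference concentrations (>= 3 pairs).
#' @param method `"bootstrap"` or `"half-range"`.
#' @param n_boot bootstrap replicates.
#' @return object of class `calibration_fit`: `slope` (reference units per
#'   cps), `rel_uncertainty` (fraction), `slope_range`, `n`.
#' @export
calibrate <- function(cps, reference, method = c("bootstrap", "half-range"),
                      n_boot = 500) {
  method <- match.arg(method)
  ok <- !is.na(cps) & !is.na(reference)
  cps <- cps[ok]; reference <- reference[ok]
  if (length(cps) < 3) stop("calibration needs at least 3 paired points")
  if (stats::sd(reference) == 0 && length(unique(reference)) == 1)
    stop("degenerate reference: all values equal")
  slope_of <- function(i) sum(reference[i] * cps[i]) / sum(cps[i]^2)
  slope <- slope_of(seq_along(cps))
  reps <- if (method == "bootstrap") {
    vapply(seq_len(n_boot), function(b)
      slope_of(sample.int(length(cps), replace = TRUE)), numeric(1))
  } else {
    vapply(seq_along(cps), function(i) slope_of(-i), numeric(1))
  }
  rng <- range(reps)
  rel <- if (method == "bootstrap") stats::sd(reps) / slope
  else diff(rng) / 2 / slope
  structure(list(slope = slope, intercept = 0, slope_range = rng,
                 rel_uncertainty = rel, method = method, n = length(cps)),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf(
    "Zero-intercept calibration: slope %.4g (range %.4g-%.4g), +/- %.1f%% (%s, n=%d)\n",
    x$slope, x$slope_range[1], x$slope_range[2],
    100 * x$rel_uncertainty, x$method, x$n))
  invisible(x)
}

#' Convert a mass-concentration sensitivity to a mixing-ratio sensitivity
#'
#' One part-per-trillion of a trace gas corresponds to
#' `molar_mass / V_m` ng m-3, with `V_m` the molar volume (litres) at the
#' reference temperature and pressure; the sensitivity in cps per ng m-3 is
#' scaled by that factor.
#'
#' @param sens_ng sensitivity, cps per ng m-3.
#' @param molar_mass g mol-1.
#' @param t temperature, degC (default 25).
#' @param p pressure, hPa (default 1013.25).
#' @return sensitivity in cps per ppt.
#' @export
#' @examples
#' sensitivity_to_ppt(0.7, 265.911)   # ~7.6, i.e. ~8 cps/ppt
sensitivity_to_ppt <- function(sens_ng, molar_mass, t = 25, p = 1013.25) {
  stopifnot(sens_ng > 0, molar_mass > 0, p > 0)
  v_m <- 8.314 * (t + 273.15) / (p * 100) * 1000   # L mol-1
  sens_ng * molar_mass / v_m
}

#' Limit of detection of an ion-counting measurement
#'
#' Counting mode: the concentration yielding at least one ion count over the
#' averaging window (`1/(sens * averaging_s)`). Noise mode: the
#' concentration equivalent of the zero-air noise (`noise_cps/sens`), which
#' includes instrument noise and is the more realistic estimate.
#'
#' @param sens sensitivity, cps per ng m-3.
#' @param averaging_s averaging time, s (counting mode).
#' @param noise_cps zero-air noise, cps (noise mode).
#' @param mode `"counting"` or `"noise"`.
#' @return LOD, ng m-3.
#' @export
lod <- function(sens, averaging_s = 1, noise_cps = NULL,
                mode = c("counting", "noise")) {
  mode <- match.arg(mode)
  stopifnot(sens > 0, averaging_s > 0)
  if (mode == "counting") return(1 / (sens * averaging_s))
  if (is.null(noise_cps)) stop("noise mode needs noise_cps")
  noise_cps / sens
}

#' Read a two-column spectrum CSV (mz, cps)
#'
#' @param path CSV path with columns `mz`, `cps`.
#' @return data.frame.
#' @export
read_spectrum_csv <- function(path) {
  sp <- utils::read.csv(path)
  if (!all(c("mz", "cps") %in% names(sp)))
    stop("spectrum CSV needs columns mz, cps")
  sp
}
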