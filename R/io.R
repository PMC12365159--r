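## File interfaces: GeoJSON source polygons, surface-state CSV, fit report
## JSON. All CSVs are RFC-4180 UTF-8 with ISO-8601 UTC timestamps.

#' Read source polygons from GeoJSON
#'
#' Planar-coordinate GeoJSON Polygon features with properties `name`,
#' `dose_g_per_ha`, `application_date` (and optionally `rel_dose`).
#'
#' @param path GeoJSON file.
#' @return a [source_map()].
#' @export
read_sources_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  feats <- gj$features
  if (is.null(feats)) stop("not a GeoJSON FeatureCollection")
  polys <- list(); dose <- c(); rel <- c(); dates <- c()
  for (f in feats) {
    if (!identical(f$geometry$type, "Polygon"))
      stop("only Polygon features are supported")
    ring <- f$geometry$coordinates[[1]]
    xy <- do.call(rbind, lapply(ring, function(p)
      c(x = as.numeric(p[[1]]), y = as.numeric(p[[2]]))))
    nm <- if (!is.null(f$properties$name)) f$properties$name
    else paste0("field_", length(polys) + 1)
    polys[[nm]] <- as.data.frame(xy)
    dose <- c(dose, if (!is.null(f$properties$dose_g_per_ha))
      f$properties$dose_g_per_ha else 0)
    rel <- c(rel, if (!is.null(f$properties$rel_dose))
      f$properties$rel_dose else 1)
    dates <- c(dates, if (!is.null(f$properties$application_date))
      f$properties$application_date else NA)
  }
  source_map(polys, dose_g_per_ha = dose, rel_dose = rel,
             application_date = dates)
}

#' Write a source map to GeoJSON
#'
#' @param sources a [source_map()].
#' @param path output file.
#' @export
write_sources_geojson <- function(sources, path) {
  feats <- lapply(sources, function(s) {
    ring <- lapply(seq_len(nrow(s$polygon)), function(i)
      c(s$polygon[i, 1], s$polygon[i, 2]))
    ring <- c(ring, ring[1])
    list(type = "Feature",
         properties = list(name = s$name,
                           dose_g_per_ha = s$dose_g_per_ha,
                           rel_dose = s$rel_dose,
                           application_date = s$application_date),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection",
                            features = unname(feats)),
                       path, auto_unbox = TRUE, digits = NA)
}

#' Write the per-step surface-state CSV
#'
#' Columns `timestamp, c_z0, p_vap_z0, p_sat, r, r_a, r_b`.
#'
#' @param state output of [surface_state()].
#' @param path output file.
#' @export
write_surface_csv <- function(state, path) {
  out <- data.frame(
    timestamp = format(state$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    c_z0 = state$c_z0, p_vap_z0 = state$p_vap_z0, p_sat = state$p_sat,
    r = state$r, r_a = state$r_a, r_b = state$r_b)
  utils::write.csv(out, path, row.names = FALSE)
}

#' Write an availability-fit report as JSON
#'
#' @param fit an `availability_fit`.
#' @param path output file.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(list(
    coefficients = as.list(fit$coefficients),
    std_errors = as.list(fit$std_errors),
    converged = fit$converged, iterations = fit$iterations,
    sigma = fit$sigma, n = fit$n), path, auto_unbox = TRUE, digits = NA)
}

#' Write a met series CSV
#'
#' @param met met data.frame.
#' @param path output file.
#' @export
write_met_csv <- function(met, path) {
  out <- data.frame(
    timestamp = format(met$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    ustar = met$ustar, obukhov_l = met$obukhov_l, wd_deg = met$wd,
    sigma_w = met$sigma_w, t_air_c = met$t_air)
  utils::write.csv(out, path, row.names = FALSE)
}
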