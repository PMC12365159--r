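## Application-dose estimation from exposed-filter contents and comparison
## between independent dose estimates (tank assay vs filter exposure).

#' Convert between g ha-1 and ng m-2
#'
#' @param x value(s) to convert.
#' @return converted value(s).
#' @export
g_ha_to_ng_m2 <- function(x) x * NG_M2_PER_G_HA

#' @rdname g_ha_to_ng_m2
#' @export
ng_m2_to_g_ha <- function(x) x / NG_M2_PER_G_HA

#' Dose estimate summary
#'
#' @param method one of `"tank"`, `"filter_top"`, `"filter_ground"`.
#' @param mean,sd dose mean and standard deviation, g ha-1.
#' @param n number of statistical units.
#' @param values optional raw per-unit doses (overrides mean/sd/n).
#' @return object of class `dose_estimate`.
#' @export
dose_estimate <- function(method = c("tank", "filter_top", "filter_ground"),
                          mean = NULL, sd = NULL, n = NULL, values = NULL) {
  method <- match.arg(method)
  if (!is.null(values)) {
    mean <- base::mean(values)
    sd <- if (length(values) > 1) stats::sd(values) else 0
    n <- length(values)
  }
  if (is.null(mean) || is.null(sd) || is.null(n))
    stop("supply values or mean/sd/n")
  if (mean < 0 || sd < 0) stop("mean and sd must be >= 0")
  structure(list(method = method, mean = mean, sd = sd, n = n,
                 values = values), class = "dose_estimate")
}

#' @export
print.dose_estimate <- function(x, ...) {
  cat(sprintf("Dose estimate (%s): %.0f +/- %.0f g/ha (n = %d)\n",
              x$method, x$mean, x$sd, x$n))
  invisible(x)
}

#' Application dose from exposed-filter contents
#'
#' Each statistical unit is a pooled pair of filters (following the
#' extraction protocol); the dose is the chlorothalonil content divided by
#' the total filter area, converted from ng m-2 to g ha-1.
#'
#' @param content_ng content per pooled unit, ng.
#' @param n_filters filters per pooled unit (default 2).
#' @param filter_diameter_m filter diameter, m (default 0.09).
#' @param method label, `"filter_top"` or `"filter_ground"`.
#' @return a [dose_estimate()] with per-unit doses in `values`.
#' @export
#' @examples
#' filter_dose(c(5.2e6, 5.6e6, 5.4e6))
filter_dose <- function(content_ng, n_filters = 2, filter_diameter_m = 0.09,
                        method = "filter_top") {
  if (!length(content_ng)) stop("empty filter input")
  if (filter_diameter_m <= 0) stop("filter area must be > 0")
  area <- n_filters * pi * (filter_diameter_m / 2)^2
  dose <- ng_m2_to_g_ha(content_ng / area)
  dose_estimate(method, values = dose)
}

#' Welch comparison of two dose estimates
#'
#' Welch two-sample t statistic from summary statistics
#' (means, standard deviations and sample sizes), with the
#' Welch-Satterthwaite degrees of freedom.
#'
#' @param a,b [dose_estimate()] objects with `n >= 2`.
#' @return list with `statistic`, `df`, `p_value`, `mean_diff`.
#' @export
compare_doses <- function(a, b) {
  stopifnot(inherits(a, "dose_estimate"), inherits(b, "dose_estimate"))
  if (a$n < 2 || b$n < 2) stop("each estimate needs n >= 2")
  va <- a$sd^2 / a$n; vb <- b$sd^2 / b$n
  if (va + vb == 0) stop("zero variance in both groups")
  t_stat <- (a$mean - b$mean) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  p <- 2 * stats::pt(-abs(t_stat), df)
  list(statistic = t_stat, df = df, p_value = p,
       mean_diff = a$mean - b$mean)
}

#' Read a filter-exposure CSV
#'
#' Columns `location, pair_id, content_ng, n_filters, filter_diameter_m`.
#'
#' @param path CSV path.
#' @param method dose-estimate label.
#' @return a [dose_estimate()].
#' @export
read_filter_csv <- function(path, method = "filter_top") {
  ff <- utils::read.csv(path)
  need <- c("content_ng", "n_filters", "filter_diameter_m")
  if (!all(need %in% names(ff)))
    stop("filter CSV needs columns ", paste(need, collapse = ", "))
  area <- ff$n_filters * pi * (ff$filter_diameter_m / 2)^2
  dose_estimate(method, values = ng_m2_to_g_ha(ff$content_ng / area))
}
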