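test_that("surface concentration and resistance flux are mutual inverses", {
  expect_equal(surface_concentration(50, 0, 40, 60), 50)
  expect_equal(surface_concentration(50, 10, 40, 60), 1050)
  set.seed(1)
  for (i in 1:20) {
    c_ref <- runif(1, 0, 200); f <- runif(1, -5, 40)
    ra <- runif(1, 10, 100); rb <- runif(1, 20, 400)
    expect_equal(resistance_flux(surface_concentration(c_ref, f, ra, rb),
                                 c_ref, ra, rb), f, tolerance = 1e-12)
  }
})

test_that("ideal-gas vapour pressure conversion is correct and linear", {
  ## one mole-mass worth of ng at 25 degC
  expect_equal(vapour_pressure(265.911, 25),
               1e-9 * 8.314 * 298.15, tolerance = 1e-6)
  expect_equal(vapour_pressure(0, 25), 0)
  expect_equal(vapour_pressure(200, 10), 2 * vapour_pressure(100, 10))
  ## round trip with its inverse
  expect_equal(conc_from_vapour_pressure(vapour_pressure(123.4, 18), 18),
               123.4, tolerance = 1e-12)
})

test_that("saturation pressure reproduces its reference point and shape", {
  expect_equal(saturation_pressure(25), 7.6e-5, tolerance = 1e-12)
  ## hand evaluation at 35 degC of the printed exponential
  expect_equal(saturation_pressure(35), 2.6416e-4, tolerance = 1e-4)
  ## degenerate activation energy
  expect_equal(saturation_pressure(c(-10, 0, 30), activation = 0),
               rep(7.6e-5, 3))
  ## strictly increasing, log-linear in 1/T_K
  tt <- seq(-5, 40, by = 2.5)
  ps <- saturation_pressure(tt)
  expect_true(all(diff(ps) > 0))
  lin <- stats::lm(log(ps) ~ I(1 / (tt + 273.15)))
  expect_lt(max(abs(stats::residuals(lin))), 1e-10)
})

test_that("availability ratio is the pressure ratio with its limits", {
  expect_equal(availability_ratio(2e-5, 2e-5), 1)
  expect_equal(availability_ratio(0, 7.6e-5), 0)
  expect_error(availability_ratio(1e-5, -1), "p_sat")
})

test_that("daily availability inferred from a synthetic campaign tracks the truth", {
  cfg <- campaign_config(n_days = 10, conc_noise = 0.05, c_bgd_sd = 0,
                         outages = list(), seed = 21)
  camp <- simulate_campaign(cfg)
  inv <- invert_flux(camp$obs$conc$conc, camp$truth$d_coeff,
                     cfg$c_bgd_mean)
  surf <- surface_state(camp$met, camp$obs$conc$conc, inv$flux)
  dr <- daily_availability(camp$met$timestamp, surf$r,
                           day_origin = camp$met$timestamp[1] + 86400)
  post <- dr$day >= 0.4
  r_exp <- cfg$r0 * (57 * exp(-0.61 * dr$day[post]) +
                       43 * exp(-0.012 * dr$day[post])) / 100
  expect_true(all(abs(dr$r[post] - r_exp) / r_exp < 0.25))
  expect_equal(stats::median(dr$r[post] / r_exp), 1, tolerance = 0.1)
})

test_that("double-exponential fit recovers noiseless generator coefficients", {
  day <- seq(0.5, 21.5, by = 1)
  y <- 57 * exp(-0.61 * day) + 43 * exp(-0.012 * day)
  fit <- fit_availability(day, y)
  co <- fit$coefficients
  expect_equal(unname(co["a1"]), 57, tolerance = 1e-4)
  expect_equal(unname(co["k1"]), 0.61, tolerance = 1e-4)
  expect_equal(unname(co["a2"]), 43, tolerance = 1e-4)
  expect_equal(unname(co["k2"]), 0.012, tolerance = 1e-4)
  expect_true(fit$converged)
  ## nested single-exponential data
  y1 <- 80 * exp(-0.45 * day)
  fit1 <- fit_availability(day, y1)
  co1 <- fit1$coefficients
  expect_equal(unname(co1["a1"] * exp(-co1["k1"] * 5) +
                        co1["a2"] * exp(-co1["k2"] * 5)),
               80 * exp(-0.45 * 5), tolerance = 1e-6)
  expect_lt(min(co1["a2"], co1["a1"]), 1)
  expect_error(fit_availability(1:5, exp(-(1:5))), "8 daily")
})

test_that("fit of the plateau variant reproduces the fixed slow rate", {
  day <- seq(0.5, 21.5, by = 1)
  y <- 22 * exp(-0.20 * day) + 78
  fit <- fit_availability(day, y, fix_k2 = 0)
  expect_equal(unname(fit$coefficients["a1"]), 22, tolerance = 1e-5)
  expect_equal(unname(fit$coefficients["k1"]), 0.20, tolerance = 1e-5)
  expect_equal(unname(fit$coefficients["a2"]), 78, tolerance = 1e-5)
  expect_identical(unname(fit$coefficients["k2"]), 0)
})

test_that("fast-rate estimate is nearly unbiased under multiplicative noise", {
  set.seed(42)
  day <- seq(0.5, 21.5, by = 1)
  mu <- 57 * exp(-0.61 * day) + 43 * exp(-0.012 * day)
  k1s <- replicate(200, {
    y <- mu * (1 + 0.05 * rnorm(length(day)))
    tryCatch(fit_availability(day, y)$coefficients[["k1"]], error = function(e) NA)
  })
  expect_lt(abs(stats::median(k1s, na.rm = TRUE) - 0.61), 0.1 * 0.61)
})

test_that("fast-rate 95 percent confidence intervals cover the truth", {
  set.seed(77)
  day <- seq(0.5, 21.5, by = 1)
  mu <- 57 * exp(-0.61 * day) + 43 * exp(-0.012 * day)
  cover <- replicate(50, {
    y <- mu * (1 + 0.05 * rnorm(length(day)))
    fit <- tryCatch(fit_availability(day, y), error = function(e) NULL)
    if (is.null(fit)) return(NA)
    k1 <- fit$coefficients[["k1"]]; se <- fit$std_errors[["k1"]]
    k1 - 1.96 * se <= 0.61 && 0.61 <= k1 + 1.96 * se
  })
  expect_gte(mean(cover, na.rm = TRUE), 0.80)
})

test_that("modelled flux reconstructs the generating flux", {
  cfg <- campaign_config(n_days = 8, outages = list(), seed = 3)
  camp <- simulate_campaign(cfg)
  met <- camp$met
  r_fun <- function(d) cfg$r0 * (57 * exp(-0.61 * pmax(d, 0)) +
                                   43 * exp(-0.012 * pmax(d, 0))) / 100
  mod <- modelled_flux(r_fun, met, conc_ref = camp$truth$c_ref,
                       day = met$day - 1)
  post <- met$day >= 1
  expect_gt(stats::cor(mod$flux[post], camp$truth$flux[post])^2, 0.9)
  ## degenerate availability
  mod0 <- modelled_flux(function(d) 0 * d, met, conc_ref = 0,
                        day = met$day - 1)
  expect_true(all(abs(mod0$flux) < 1e-12))
  ## p_sat monotonicity: warm midday beats cold night at equal r and
  ## resistances
  expect_gt(
    modelled_flux(function(d) 0.1, transform(met[1, ], t_air = 25),
                  conc_ref = 0, day = 1)$flux,
    modelled_flux(function(d) 0.1, transform(met[1, ], t_air = 5),
                  conc_ref = 0, day = 1)$flux)
})

test_that("cumulation arithmetic and gap-filling behave", {
  ts <- as.POSIXct("2018-04-17", tz = "UTC") + seq(0, 86400, by = 1800)
  ## constant 11.574 ng m-2 s-1 for one day over 100 g/ha is ~10 percent
  cum <- cumulate_flux(ts, rep(11.574, length(ts)), dose_g_per_ha = 100)
  expect_equal(tail(cum$cum_pct, 1), 11.574 * 86400 / 1e7 * 100,
               tolerance = 1e-10)
  expect_equal(tail(cum$cum_pct, 1), 10, tolerance = 0.01)
  expect_true(all(diff(cum$cum_pct) >= 0))
  ## without gaps, gap-filling changes nothing
  meas <- 10 + sin(seq_along(ts) / 4)
  gf <- gapfill_and_cumulate(ts, meas, meas * 0.8, dose_g_per_ha = 100)
  expect_equal(gf$filled$flux, meas)
  expect_equal(tail(gf$cumulative$cum_pct, 1),
               tail(cumulate_flux(ts, meas, 100)$cum_pct, 1))
  expect_error(gapfill_flux(ts, rep(NA_real_, length(ts)), meas),
               "overlap")
})

test_that("an outage gap-filled with the modelled flux lands near the truth", {
  cfg <- campaign_config(n_days = 10, conc_noise = 0, c_bgd_sd = 0,
                         outages = list(c(4, 7)), seed = 13)
  camp <- simulate_campaign(cfg)
  inv <- invert_flux(camp$obs$conc$conc, camp$truth$d_coeff,
                     cfg$c_bgd_mean)
  r_fun <- function(d) cfg$r0 * (57 * exp(-0.61 * pmax(d, 0)) +
                                   43 * exp(-0.012 * pmax(d, 0))) / 100
  mod <- modelled_flux(r_fun, camp$met,
                       conc_ref = ifelse(is.na(camp$obs$conc$conc),
                                         cfg$c_bgd_mean,
                                         camp$obs$conc$conc),
                       day = camp$met$day - 1)
  mod$flux[camp$met$day < 1] <- 0
  gf <- gapfill_and_cumulate(camp$met$timestamp, inv$flux, mod$flux,
                             dose_g_per_ha = cfg$dose_g_per_ha)
  truth_cum <- tail(cumulate_flux(camp$met$timestamp, camp$truth$flux,
                                  cfg$dose_g_per_ha)$cum_pct, 1)
  expect_equal(tail(gf$cumulative$cum_pct, 1), truth_cum,
               tolerance = 0.15)
  expect_true(any(gf$filled$method == "gapfilled"))
})

test_that("dissipation budget sums first-order pathways", {
  b <- dissipation_budget()
  expect_equal(b$total, sum(b$components))
  expect_equal(b$total, 0.57, tolerance = 1e-12)
  expect_error(dissipation_budget(volatilisation = -0.1), ">= 0")
})

test_that("surface-state CSV and fit JSON writers produce readable artefacts", {
  cfg <- campaign_config(n_days = 2, outages = list(), seed = 8)
  camp <- simulate_campaign(cfg)
  surf <- surface_state(camp$met, camp$truth$c_ref, camp$truth$flux)
  f <- withr::local_tempfile(fileext = ".csv")
  write_surface_csv(surf, f)
  back <- utils::read.csv(f)
  expect_named(back, c("timestamp", "c_z0", "p_vap_z0", "p_sat", "r",
                       "r_a", "r_b"))
  day <- seq(0.5, 21.5)
  fit <- fit_availability(day, 57 * exp(-0.61 * day) + 43)
  fj <- withr::local_tempfile(fileext = ".json")
  write_fit_json(fit, fj)
  rep <- jsonlite::read_json(fj)
  expect_true(rep$converged)
  expect_equal(rep$coefficients$k1, 0.61, tolerance = 1e-3)
})
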