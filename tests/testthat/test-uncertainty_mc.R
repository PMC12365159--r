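zero_var_spec <- function(n_draws = 10)
  mc_spec(z0_sd = 0, d_sd = 0, sensor_sd = c(0, 0, 0), ustar_pct = 0,
          obukhov_pct = 0, sigma_w_pct = 0, conc_pct = 0, wd_sd = 0,
          c_bgd_sd = 0, n_draws = n_draws)

test_that("degenerate distributions return the means", {
  set.seed(1)
  p <- sample_parameters(zero_var_spec(), n = 50)
  expect_true(all(p$z0 == 0.0035))
  expect_true(all(p$f_ustar == 1) && all(p$f_l == 1))
  expect_true(all(p$wd_err == 0) && all(p$dx == 0))
  expect_true(all(p$c_bgd == 5.7))
})

test_that("sampled distributions match their specification", {
  set.seed(2)
  p <- sample_parameters(mc_spec(), n = 1e5)
  ## log-normal z0 parameterised by its arithmetic mean
  expect_equal(mean(p$z0), 0.0035, tolerance = 0.01)
  expect_equal(stats::sd(p$z0), 4e-4, tolerance = 0.05)
  expect_true(all(p$z0 > 0))
  ## circular standard deviation of the wind-direction error
  th <- p$wd_err * pi / 180
  rbar <- sqrt(mean(cos(th))^2 + mean(sin(th))^2)
  circ_sd <- sqrt(-2 * log(rbar)) * 180 / pi
  expect_equal(circ_sd, 12.5, tolerance = 0.05)
  ## multiplicative factors keep physics valid
  expect_true(all(p$f_ustar > 0) && all(p$f_l > 0))
})

test_that("zero-variance Monte-Carlo collapses onto the deterministic flux", {
  cfg <- campaign_config(n_days = 2, conc_noise = 0, c_bgd_sd = 0,
                         outages = list(), seed = 5)
  camp <- simulate_campaign(cfg)
  conc <- camp$truth$d_coeff * camp$truth$flux + cfg$c_bgd_mean
  set.seed(3)
  mcr <- mc_flux(camp$met, conc, camp$sources, camp$receptor,
                 spec = zero_var_spec(5), mode = "step")
  det <- invert_flux(conc, camp$truth$d_coeff, cfg$c_bgd_mean)
  ok <- !is.na(mcr$summary$flux) & det$method == "inversion"
  expect_true(any(ok))
  expect_equal(mcr$summary$flux[ok], det$flux[ok], tolerance = 1e-9)
  expect_equal(mcr$summary$p05[ok], mcr$summary$p95[ok], tolerance = 1e-9)
})

test_that("concentration-only uncertainty matches linear propagation on one step", {
  cfg <- campaign_config(n_days = 2, conc_noise = 0, c_bgd_sd = 0,
                         outages = list(), seed = 5)
  camp <- simulate_campaign(cfg)
  i <- which.max(camp$truth$flux)
  spec <- zero_var_spec(4000); spec$conc_pct <- 0.14
  conc_i <- camp$truth$d_coeff[i] * camp$truth$flux[i] + cfg$c_bgd_mean
  set.seed(4)
  mcr <- mc_flux(camp$met[i, ], conc_i, camp$sources, camp$receptor,
                 spec = spec, mode = "step")
  ## delta method: sd(F) = 0.14 |C| / D; 90 percent band half-width is
  ## 1.645 sd
  sd_theory <- 0.14 * conc_i / camp$truth$d_coeff[i]
  half <- (mcr$summary$p95[1] - mcr$summary$p05[1]) / 2
  expect_equal(half, 1.645 * sd_theory, tolerance = 0.05)
})

test_that("wider input uncertainty widens the flux bands", {
  cfg <- campaign_config(n_days = 2, outages = list(), seed = 6)
  camp <- simulate_campaign(cfg)
  conc <- camp$truth$d_coeff * camp$truth$flux + cfg$c_bgd_mean
  run_width <- function(scale) {
    sp <- mc_spec(z0_sd = 0.0004 * scale, d_sd = 0.03 * scale,
                  sensor_sd = c(1, 1, 0.1) * scale,
                  ustar_pct = 0.14 * scale, obukhov_pct = 0.40 * scale,
                  sigma_w_pct = 0.14 * scale, conc_pct = 0.14 * scale,
                  wd_sd = 12.5 * scale, c_bgd_sd = 2.2 * scale,
                  n_draws = 60)
    set.seed(7)
    s <- mc_flux(camp$met, conc, camp$sources, camp$receptor, spec = sp,
                 mode = "step")$summary
    mean(s$p95 - s$p05, na.rm = TRUE)
  }
  expect_gt(run_width(1), run_width(0.5))
})

test_that("percentiles are ordered and seeded runs are bit-reproducible", {
  cfg <- campaign_config(n_days = 2, outages = list(), seed = 8)
  camp <- simulate_campaign(cfg)
  conc <- camp$obs$conc$conc
  run <- function() {
    set.seed(99)
    mc_flux(camp$met, conc, camp$sources, camp$receptor,
            spec = mc_spec(n_draws = 20), mode = "step")
  }
  a <- run(); b <- run()
  expect_identical(a$draws, b$draws)
  ok <- !is.na(a$summary$flux)
  expect_true(all(a$summary$p05[ok] <= a$summary$flux[ok] + 1e-12))
  expect_true(all(a$summary$flux[ok] <= a$summary$p95[ok] + 1e-12))
})

test_that("cumulative percentiles are taken over whole trajectories", {
  ts <- as.POSIXct("2018-04-17", tz = "UTC") + seq(0, 3 * 86400, by = 1800)
  n <- length(ts)
  ## deterministic draws: all bands equal the single trajectory
  dr <- matrix(rep(5, n * 8), n, 8)
  mc <- mc_cumulative(dr, ts, dose_g_per_ha = 100)
  expect_equal(unname(mc$final["p05"]), unname(mc$final["mean"]))
  expect_equal(unname(mc$final["p95"]), unname(mc$final["mean"]))
  ## doubling the dose halves every percentage
  mc2 <- mc_cumulative(dr, ts, dose_g_per_ha = 200)
  expect_equal(unname(mc2$final), unname(mc$final) / 2, tolerance = 1e-12)
  ## trajectory percentiles differ from per-step percentile integration
  set.seed(5)
  scale <- runif(30, 0.5, 1.5)
  drs <- matrix(5, n, 30) %*% diag(scale)
  mcs <- mc_cumulative(drs, ts, dose_g_per_ha = 100)
  expect_lt(mcs$final["p05"], mcs$final["mean"])
  expect_gt(mcs$final["p95"], mcs$final["mean"])
  expect_equal(unname(mcs$final["p95"] / mcs$final["p05"]),
               unname(stats::quantile(scale, 0.95) /
                        stats::quantile(scale, 0.05)),
               tolerance = 1e-9)
})

test_that("yaml Monte-Carlo specs are read with defaults filled in", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("z0: {mean: 0.004, sd: 0.0005}",
               "ustar: {pct: 0.10}",
               "c_bgd: {mean: 4.5, sd: 1.0}",
               "n_draws: 25"), f)
  sp <- read_mc_spec(f)
  expect_equal(sp$z0_mean, 0.004)
  expect_equal(sp$ustar_pct, 0.10)
  expect_equal(sp$obukhov_pct, 0.40)  # default retained
  expect_equal(sp$c_bgd_mean, 4.5)
  expect_equal(sp$n_draws, 25)
  expect_error(mc_spec(n_draws = 1), "n_draws")
  expect_error(mc_spec(z0_sd = -1), ">= 0")
})
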