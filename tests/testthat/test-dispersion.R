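test_that("power-law profiles match the similarity profiles they are fit to", {
  pl <- powerlaw_profile_params(0.3, 1e6, 0.0035, 0.33, z_ref = 1.9)
  ## wind exponent vs an independent finite difference of the log profile
  z1 <- 1.57; z2 <- 0.157
  u_mo <- function(z) 0.3 / 0.4 * log(z / 0.0035)
  p_fd <- (log(u_mo(z1)) - log(u_mo(z2))) / (log(z1) - log(z2))
  expect_equal(pl$p, p_fd, tolerance = 1e-5)
  ## diffusivity matching condition at z_ref (neutral phi_H = 1)
  expect_equal(pl$b * z1^pl$n, 0.4 * 0.3 * z1, tolerance = 1e-4)
  ## stable stratification steepens the wind profile
  pls <- powerlaw_profile_params(0.3, 50, 0.0035, 0.33, z_ref = 1.9)
  expect_gt(pls$p, pl$p)
  expect_error(powerlaw_profile_params(-0.1, 1e6, 0.0035, 0.33), "ustar")
})

test_that("strip dispersion agrees with a numerical solution of the
           advection-diffusion equation", {
  pl <- powerlaw_profile_params(0.3, 1e6, 0.0035, 0.33, z_ref = 1.9)
  d_ana <- strip_dispersion_coeff(200, 1.9, 0.3, 1e6, 0.0035, 0.33)
  d_num <- pde_dispersion_oracle(200, 1.9 - 0.33, pl)
  expect_equal(d_ana, d_num, tolerance = 0.10)
})

test_that("the dispersion kernel conserves mass at the downwind edge", {
  pl <- powerlaw_profile_params(0.3, 1e6, 0.0035, 0.33, z_ref = 1.9)
  fetch <- 200
  ## integral of u(z) C(z) over z must equal fetch x unit flux
  f <- function(z) {
    (pl$a * (z - 0.33)^pl$p) *
      strip_dispersion_coeff(fetch, z, 0.3, 1e6, 0.0035, 0.33, z_ref = 1.9)
  }
  mass <- stats::integrate(Vectorize(f), 0.33 + 1e-4, fetch,
                           rel.tol = 1e-7)$value
  expect_equal(mass / fetch, 1, tolerance = 0.02)
})

test_that("strip dispersion has the required limits and monotonicity", {
  expect_identical(strip_dispersion_coeff(0, 1.9, 0.3, 1e6, 0.0035, 0.33),
                   0)
  fs <- c(10, 50, 200, 800)
  ds <- strip_dispersion_coeff(fs, 1.9, 0.3, 1e6, 0.0035, 0.33)
  expect_true(all(ds >= 0))
  expect_true(all(diff(ds) > 0))
  ## D vanishes far above the plume
  zs <- c(1.9, 5, 20, 60)
  dz <- vapply(zs, function(z)
    strip_dispersion_coeff(200, z, 0.3, 1e6, 0.0035, 0.33, z_ref = 1.9),
    numeric(1))
  expect_true(all(diff(dz) < 0))
  expect_lt(dz[4] / dz[1], 0.05)
})

test_that("polygon dispersion is invariant under a common frame rotation", {
  met <- neutral_met()
  poly <- square_poly(0, -210, 400)
  rot <- function(xy, ang) {
    th <- ang * pi / 180
    data.frame(x = xy$x * cos(th) - xy$y * sin(th),
               y = xy$x * sin(th) + xy$y * cos(th))
  }
  d0 <- polygon_dispersion(c(0, 0, 1.9), source_map(list(a = poly)),
                           0.3, 1e6, 180, 0.0035, 0.33)$d_coeff
  for (ang in c(37, 120, 261)) {
    ## rotating geometry by +ang (counterclockwise) shifts the
    ## meteorological bearing by -ang
    d1 <- polygon_dispersion(c(0, 0, 1.9),
                             source_map(list(a = rot(poly, ang))),
                             0.3, 1e6, (180 - ang) %% 360, 0.0035,
                             0.33)$d_coeff
    expect_equal(d1, d0, tolerance = 1e-9)
  }
})

test_that("a receptor deep inside a large source reduces to the strip solution", {
  ## receptor 40 m inside the downwind edge of a 450 m square: upwind fetch
  ## 410 m of emitting surface, laterally wide
  poly <- square_poly(0, -185, 450)
  d_poly <- polygon_dispersion(c(0, 0, 1.9), source_map(list(a = poly)),
                               0.3, 1e6, 180, 0.0035, 0.33)$d_coeff
  d_strip <- strip_dispersion_coeff(410, 1.9, 0.3, 1e6, 0.0035, 0.33)
  expect_equal(d_poly, d_strip, tolerance = 0.05)
})

test_that("source attribution behaves under symmetry, distance and dose scaling", {
  met <- neutral_met()
  ## single emitting polygon
  one <- polygon_dispersion(c(0, 0, 1.9),
                            source_map(list(a = square_poly(0, -200, 300))),
                            0.3, 1e6, 180, 0.0035, 0.33)
  expect_equal(unname(one$contributions), 1)
  ## two identical polygons symmetric about the wind axis (gaussian mode)
  sym <- source_map(list(l = square_poly(-150, -300, 180),
                         r = square_poly(150, -300, 180)))
  two <- polygon_dispersion(c(0, 0, 1.9), sym, 0.3, 1e6, 180, 0.0035,
                            0.33, sigma_w = 0.39, mode = "gaussian")
  expect_equal(two$contributions[["l"]], two$contributions[["r"]],
               tolerance = 1e-9)
  expect_equal(sum(two$contributions), 1, tolerance = 1e-9)
  ## co-located sources with dose factors 1 and 0.68 split proportionally
  co <- source_map(list(a = square_poly(0, -200, 300),
                        b = square_poly(0, -200, 300)),
                   rel_dose = c(1, 0.68))
  cc <- polygon_dispersion(c(0, 0, 1.9), co, 0.3, 1e6, 180, 0.0035, 0.33)
  expect_equal(unname(cc$contributions["b"] / cc$contributions["a"]), 0.68,
               tolerance = 1e-9)
  ## a distant second field contributes little, less so with distance
  contrib_at <- function(dist) {
    sm <- source_map(list(near = square_poly(0, -185, 450),
                          far = square_poly(0, -dist, 450)))
    polygon_dispersion(c(0, 0, 1.9), sm, 0.3, 1e6, 180, 0.0035,
                       0.33)$contributions[["far"]]
  }
  cs <- vapply(c(1000, 2000, 4000), contrib_at, numeric(1))
  expect_true(all(diff(cs) < 0))
  expect_lt(cs[1], 0.2)
})

test_that("contributions over a met series sum to one where defined", {
  cfg <- campaign_config(n_days = 2, seed = 4)
  met <- generate_met(cfg)
  sm <- source_map(list(a = square_poly(0, -185, 450),
                        b = square_poly(-300, -600, 200)))
  ds <- dispersion_series(met, sm, c(0, 0, 1.9))
  tot <- ds$contrib_a + ds$contrib_b
  ok <- !is.na(tot) & ds$d_coeff > 0
  expect_true(all(abs(tot[ok] - 1) < 1e-9))
})

test_that("geojson source maps round-trip", {
  sm <- source_map(list(a = square_poly(0, -200, 300),
                        b = square_poly(500, -800, 200)),
                   dose_g_per_ha = c(544, 370), rel_dose = c(1, 0.68),
                   application_date = c("2018-04-17", "2018-04-29"))
  f <- withr::local_tempfile(fileext = ".geojson")
  write_sources_geojson(sm, f)
  back <- read_sources_geojson(f)
  expect_equal(names(back), names(sm))
  expect_equal(back$a$polygon, sm$a$polygon)
  expect_equal(back$b$rel_dose, 0.68)
  expect_equal(polygon_area(back$b$polygon), 200^2)
})
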