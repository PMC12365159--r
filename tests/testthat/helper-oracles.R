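## Independent numerical oracles and small fixtures used across tests.

## Brute-force finite-volume solution of the steady advection-diffusion
## equation  d(u c)/dx = d/dz (K dc/dz)  with power-law profiles
## u = a z^p, K = b z^n, a unit surface-flux source over 0 < x < fetch and
## a reflecting top. Implicit marching in x, Thomas tridiagonal solve.
## Independent of the package's analytical dispersion kernel.
pde_dispersion_oracle <- function(fetch, z_rec, pl, nz = 300, nx = 3000,
                                  z_top = 100, z_bot = 1e-3) {
  zg <- exp(seq(log(z_bot), log(z_top), length.out = nz))
  zf <- sqrt(zg[-1] * zg[-nz])
  u <- pl$a * zg^pl$p
  kf <- pl$b * zf^pl$n
  zb <- c(z_bot^2 / zf[1], zf, z_top)
  dz <- diff(zb)
  dx <- fetch / nx
  cvec <- numeric(nz)
  lo <- up <- di <- numeric(nz)
  for (i in 1:nz) {
    kl <- if (i > 1) kf[i - 1] / (zg[i] - zg[i - 1]) else 0
    ku <- if (i < nz) kf[i] / (zg[i + 1] - zg[i]) else 0
    lo[i] <- -kl / dz[i]; up[i] <- -ku / dz[i]
    di[i] <- u[i] / dx + (kl + ku) / dz[i]
  }
  for (s in 1:nx) {
    rhs <- u * cvec / dx
    rhs[1] <- rhs[1] + 1 / dz[1]
    cp <- numeric(nz); dp <- numeric(nz)
    cp[1] <- up[1] / di[1]; dp[1] <- rhs[1] / di[1]
    for (i in 2:nz) {
      m <- di[i] - lo[i] * cp[i - 1]
      cp[i] <- up[i] / m
      dp[i] <- (rhs[i] - lo[i] * dp[i - 1]) / m
    }
    cvec[nz] <- dp[nz]
    for (i in (nz - 1):1) cvec[i] <- dp[i] - cp[i] * cvec[i + 1]
  }
  stats::approx(zg, cvec, xout = z_rec)$y
}

## one neutral reference met state used by several dispersion tests
neutral_met <- function(n = 1) {
  data.frame(
    timestamp = as.POSIXct("2018-04-17 12:00:00", tz = "UTC") +
      1800 * (seq_len(n) - 1),
    ustar = 0.3, obukhov_l = 1e6, wd = 180, sigma_w = 0.39,
    t_air = 15, z0 = 0.0035, d = 0.33, h_c = 0.5)
}

## square polygon helper (side s, centred at cx, cy)
square_poly <- function(cx, cy, s) {
  data.frame(x = cx + c(-1, 1, 1, -1) * s / 2,
             y = cy + c(-1, -1, 1, 1) * s / 2)
}
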