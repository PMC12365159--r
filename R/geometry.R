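## Minimal planar polygon routines (local metric coordinates, x east, y north).
## Polygons are matrices/data.frames with columns x, y; simple (non-self-
## intersecting), either orientation, not necessarily closed.

poly_xy <- function(poly) {
  if (is.data.frame(poly)) poly <- as.matrix(poly[, c("x", "y")])
  storage.mode(poly) <- "double"
  n <- nrow(poly)
  if (n >= 3 && poly[1, 1] == poly[n, 1] && poly[1, 2] == poly[n, 2])
    poly <- poly[-n, , drop = FALSE]
  if (nrow(poly) < 3) stop("polygon needs at least 3 distinct vertices")
  poly
}

#' Polygon area (shoelace formula)
#'
#' @param poly matrix or data.frame with columns `x`, `y` (m).
#' @return area in m2 (always positive).
#' @export
polygon_area <- function(poly) {
  p <- poly_xy(poly)
  x <- p[, 1]; y <- p[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Point-in-polygon test (even-odd rule)
#'
#' @param px,py point coordinates, m.
#' @param poly polygon (columns `x`, `y`).
#' @return logical.
#' @export
point_in_polygon <- function(px, py, poly) {
  p <- poly_xy(poly)
  n <- nrow(p)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    if (((p[i, 2] > py) != (p[j, 2] > py)) &&
        (px < (p[j, 1] - p[i, 1]) * (py - p[i, 2]) /
           (p[j, 2] - p[i, 2]) + p[i, 1]))
      inside <- !inside
    j <- i
  }
  inside
}

## Intervals of the parameter t > 0 for which the ray (ox,oy) + t*(dx,dy)
## lies inside the polygon. Returns a 2-column matrix (t_near, t_far);
## zero rows if the ray misses. Robust for simple polygons via crossing sort.
ray_polygon_intervals <- function(ox, oy, dx, dy, poly) {
  p <- poly_xy(poly)
  n <- nrow(p)
  ts <- numeric(0)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ex <- p[j, 1] - p[i, 1]; ey <- p[j, 2] - p[i, 2]
    den <- dx * ey - dy * ex
    if (abs(den) < 1e-14) next             # parallel edge
    wx <- p[i, 1] - ox; wy <- p[i, 2] - oy
    t <- (wx * ey - wy * ex) / den         # along ray
    s <- (wx * dy - wy * dx) / den         # along edge [0,1)
    if (s >= 0 && s < 1 && t > 1e-12) ts <- c(ts, t)
  }
  if (!length(ts)) {
    if (point_in_polygon(ox, oy, p))
      stop("ray/polygon inconsistency")    # cannot happen for simple polygons
    return(matrix(numeric(0), ncol = 2))
  }
  ts <- sort(ts)
  inside0 <- point_in_polygon(ox, oy, p)
  if (inside0) ts <- c(0, ts)
  if (length(ts) %% 2 == 1) ts <- c(ts, ts[length(ts)])  # grazing contact
  matrix(ts, ncol = 2, byrow = TRUE)
}

## Crosswind intervals: intersections of the line {(x0, y) : y} (in a frame
## where +x is upwind) with the polygon, i.e. the polygon's y-coverage at
## downwind-distance x0. Returns 2-column matrix (y_lo, y_hi).
crosswind_intervals <- function(x0, poly) {
  p <- poly_xy(poly)
  n <- nrow(p)
  ys <- numeric(0)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    x1 <- p[i, 1]; x2 <- p[j, 1]
    if ((x1 > x0) == (x2 > x0)) next
    w <- (x0 - x1) / (x2 - x1)
    ys <- c(ys, p[i, 2] + w * (p[j, 2] - p[i, 2]))
  }
  if (length(ys) < 2) return(matrix(numeric(0), ncol = 2))
  ys <- sort(ys)
  if (length(ys) %% 2 == 1) ys <- ys[-length(ys)]
  matrix(ys, ncol = 2, byrow = TRUE)
}

## Rotate points into the wind frame: +x axis points upwind (towards the
## direction the wind comes from, meteorological bearing wd in deg/N).
to_wind_frame <- function(x, y, ox, oy, wd) {
  th <- wd * pi / 180
  ux <- sin(th); uy <- cos(th)      # unit vector pointing upwind
  rx <- x - ox; ry <- y - oy
  cbind(x = rx * ux + ry * uy, y = -rx * uy + ry * ux)
}
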