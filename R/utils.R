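# Internal geometry helpers. All lengths in nm, all angles in degrees unless
# a suffix says otherwise.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' @noRd
rot2 <- function(theta_deg) {
  t <- deg2rad(theta_deg)
  matrix(c(cos(t), sin(t), -sin(t), cos(t)), 2, 2)
}

# rotate points (matrix or data frame cols x,y) about a centre
rotate_xy <- function(x, y, theta_deg, cx = 0, cy = 0) {
  t <- deg2rad(theta_deg)
  dx <- x - cx; dy <- y - cy
  list(x = cx + cos(t) * dx - sin(t) * dy,
       y = cy + sin(t) * dx + cos(t) * dy)
}

# wrap an angle into (-period/2, period/2]
wrap_angle <- function(x, period = 360) {
  y <- x %% period
  y[y > period / 2] <- y[y > period / 2] - period
  y
}

# circular mean of angles with given period (degrees)
circ_mean <- function(theta, period = 60) {
  k <- 360 / period
  rad2deg(atan2(mean(sin(deg2rad(theta * k))), mean(cos(deg2rad(theta * k))))) / k
}

# minimum pairwise distance between two point sets (m x 2, n x 2)
min_cross_dist <- function(p, q) {
  if (nrow(p) == 0L || nrow(q) == 0L) return(Inf)
  d2 <- outer(p[, 1], q[, 1], "-")^2 + outer(p[, 2], q[, 2], "-")^2
  sqrt(min(d2))
}

# signed polygon area (shoelace); positive for counter-clockwise boundaries
polygon_area <- function(x, y) {
  n <- length(x)
  j <- c(2:n, 1L)
  sum(x * y[j] - x[j] * y) / 2
}

`%||%` <- function(a, b) if (is.null(a)) b else a
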