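# Shared independent oracles and fixtures, built in code.

# Rigid-body transform: rotation by Euler angles (radians) then translation.
rigid_transform <- function(P, angles = c(0.3, -0.7, 1.1),
                            translation = c(5, -3, 12)) {
  cx <- cos(angles[1]); sx <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cz <- cos(angles[3]); sz <- sin(angles[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
  sweep(P %*% t(Rz %*% Ry %*% Rx), 2, translation, "+")
}

# Apply a rigid transform to the coordinate columns of a pore-loop set.
rigid_transform_pls <- function(pls, ...) {
  P <- rigid_transform(as.matrix(pls[, c("x", "y", "z")]), ...)
  pls$x <- P[, 1]; pls$y <- P[, 2]; pls$z <- P[, 3]
  pls
}

# Brute-force aperture oracle: grid search for the largest axis-centered
# circle radius such that no point lies inside it.
aperture_oracle <- function(P, axis = c(0, 0, 1), axis_point = c(0, 0, 0),
                            resolution = 0.01) {
  a <- axis / sqrt(sum(axis^2))
  Q <- sweep(P, 2, axis_point)
  axial <- drop(Q %*% a)
  rad <- sqrt(rowSums((Q - outer(axial, a))^2))
  grid <- seq(0, max(rad), by = resolution)
  2 * max(grid[vapply(grid, function(g) all(rad >= g - 1e-12), logical(1))])
}

# Deterministic count of productive transitions before a stall, by repeated
# application of advance_motor (k_escape = 0).
steps_to_stall <- function(dead, seam, max_steps = 100) {
  st <- init_motor_state(dead, seam)
  p <- motor_params()
  steps <- 0L
  for (i in seq_len(max_steps)) {
    out <- advance_motor(st, p)
    st <- out$state
    if (out$event == "stall") return(steps)
    steps <- steps + 1L
  }
  Inf
}

# Planar two-ring fixture with a programmed pore tilt (degrees): hexagonal
# rings separated axially by `h`, the upper one displaced by h * tan(tilt).
two_ring_fixture <- function(tilt_deg, h = 28, radius = 12, jitter_sd = 0,
                             n = 6) {
  ang <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  ring <- cbind(radius * cos(ang), radius * sin(ang), 0)
  d <- h * tan(tilt_deg * pi / 180)
  r1 <- ring
  r2 <- sweep(ring, 2, c(d, 0, h), "+")
  if (jitter_sd > 0) {
    r1 <- r1 + matrix(rnorm(3 * n, 0, jitter_sd), n)
    r2 <- r2 + matrix(rnorm(3 * n, 0, jitter_sd), n)
  }
  list(ring1 = r1, ring2 = r2)
}
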