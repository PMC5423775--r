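# Small 3D helpers ----------------------------------------------------------

.as_xyz <- function(points) {
  if (is.matrix(points)) {
    if (ncol(points) != 3L) stop("coordinate matrix must have 3 columns")
    return(unname(points))
  }
  if (is.data.frame(points)) {
    if (!all(c("x", "y", "z") %in% names(points)))
      stop("coordinate data frame must have columns x, y, z")
    return(unname(as.matrix(points[, c("x", "y", "z")])))
  }
  stop("`points` must be an n x 3 matrix or a data frame with x, y, z")
}

.unit <- function(v) {
  nv <- sqrt(sum(v^2))
  if (nv == 0) stop("cannot normalize a zero vector")
  v / nv
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Orthonormal basis perpendicular to unit vector a (right-handed: u, v, a).
.perp_basis <- function(a) {
  u0 <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- .unit(u0 - sum(u0 * a) * a)
  list(u = u, v = .cross3(a, u))
}

#' Extract coordinates for one loop from a pore-loop set
#'
#' @param points A `"pore_loop_set"` data frame.
#' @param loop Loop label to extract.
#' @param protomers Optional protomer indices to keep (e.g. to drop the seam).
#' @return An n x 3 matrix ordered by protomer index.
#' @export
pore_loop_coords <- function(points, loop, protomers = NULL) {
  if (!all(c("protomer", "loop") %in% names(points)))
    stop("`points` must have columns protomer and loop")
  sel <- points[points$loop == loop, , drop = FALSE]
  if (!is.null(protomers)) sel <- sel[sel$protomer %in% protomers, , drop = FALSE]
  sel <- sel[order(sel$protomer), , drop = FALSE]
  if (anyDuplicated(sel$protomer))
    stop("pore-loop set must have exactly one point per (protomer, loop)")
  .as_xyz(sel)
}

# Helix sub-fit for a fixed axis direction: rise by a linear fit of the axial
# coordinate on index, circle center by the algebraic (Kasa) fit in the
# perpendicular plane, twist by a linear fit of the unwrapped polar angle on
# index. Returns NULL when the in-plane projection is degenerate.
.helix_given_axis <- function(P, a) {
  m <- nrow(P)
  idx <- 0:(m - 1L)
  z <- drop(P %*% a)
  rise <- stats::cov(z, idx) / stats::var(idx)
  if (rise < 0) {
    a <- -a
    z <- -z
    rise <- -rise
  }
  z0 <- mean(z) - rise * mean(idx)

  b <- .perp_basis(a)
  x <- drop(P %*% b$u)
  y <- drop(P %*% b$v)
  A <- cbind(2 * x, 2 * y, 1)
  sol <- tryCatch(qr.solve(A, x^2 + y^2), error = function(e) NULL)
  if (is.null(sol) || sol[3] + sol[1]^2 + sol[2]^2 <= 0) return(NULL)
  cx <- sol[1]; cy <- sol[2]
  R <- sqrt(sol[3] + cx^2 + cy^2)
  th <- atan2(y - cy, x - cx)
  for (i in seq_along(th)[-1]) {
    dth <- (th[i] - th[i - 1L] + pi) %% (2 * pi) - pi
    th[i] <- th[i - 1L] + dth
  }
  twist_rad <- stats::cov(th, idx) / stats::var(idx)
  phase <- mean(th) - twist_rad * mean(idx)

  z_hat <- z0 + rise * idx
  th_hat <- phase + twist_rad * idx
  c3 <- cx * b$u + cy * b$v
  Pfit <- t(vapply(seq_len(m), function(i)
    c3 + z_hat[i] * a + R * (cos(th_hat[i]) * b$u + sin(th_hat[i]) * b$v),
    numeric(3)))
  list(axis = a, axis_point = c3, rise = rise,
       twist = twist_rad * 180 / pi, radius = R,
       rms = sqrt(mean(rowSums((P - Pfit)^2))))
}

# Exact conditional helix fit for a fixed axis direction and twist: the
# axial line (z0, rise) and the in-plane model
#   x_i = cx + A cos(i tau) - B sin(i tau)
#   y_i = cy + A sin(i tau) + B cos(i tau)
# (A = R cos phi, B = R sin phi) are both linear least-squares problems, so
# for given (axis, tau) the remaining parameters and the 3D RMS residual are
# available in closed form.
.helix_conditional <- function(P, a, tau) {
  m <- nrow(P)
  idx <- 0:(m - 1L)
  z <- drop(P %*% a)
  rise <- stats::cov(z, idx) / stats::var(idx)
  z0 <- mean(z) - rise * mean(idx)
  rz <- z - (z0 + rise * idx)

  b <- .perp_basis(a)
  x <- drop(P %*% b$u)
  y <- drop(P %*% b$v)
  ci <- cos(idx * tau)
  si <- sin(idx * tau)
  X <- rbind(cbind(1, 0, ci, -si),
             cbind(0, 1, si, ci))
  obs <- c(x, y)
  beta <- tryCatch(unname(qr.solve(X, obs)), error = function(e) NULL)
  if (is.null(beta)) return(NULL)
  rxy <- obs - drop(X %*% beta)
  list(axis = a, basis = b, cx = beta[1], cy = beta[2],
       radius = sqrt(beta[3]^2 + beta[4]^2),
       rise = rise, tau = tau,
       rms = sqrt((sum(rz^2) + sum(rxy^2)) / m))
}

# Least-squares helix through m ordered points (indices 0..m-1). Seeded by a
# staged fit (axis from the null space of the second differences, which lie
# in the plane perpendicular to the axis for an ideal helix; twist from the
# unwrapped polar angles), then refined by Nelder-Mead over two axis-tilt
# angles and the twist, with all other parameters solved conditionally.
.helix_ls <- function(P) {
  m <- nrow(P)
  if (m < 4L) stop("helix fit needs at least 4 points")
  d <- diff(P)
  cr <- vapply(seq_len(nrow(d) - 1L), function(i)
    sqrt(sum(.cross3(d[i, ], d[i + 1L, ])^2)), numeric(1))
  if (all(cr < 1e-9 * max(1, max(abs(P)))))
    stop("degenerate input: points are collinear")
  e <- diff(d)
  a0 <- svd(e)$v[, 3L]
  staged <- .helix_given_axis(P, a0)
  if (is.null(staged)) stop("degenerate circle fit: points project to a line")
  a0 <- staged$axis                      # oriented so rise >= 0

  # canonical frame derived from the data (centroid at the origin, staged
  # axis along +z, in-plane basis from the first point): the refinement then
  # performs identical arithmetic whatever the input frame, which keeps the
  # fit rigid-motion invariant down to rounding error
  c0 <- colMeans(P)
  u0 <- P[1L, ] - c0
  u0 <- u0 - sum(u0 * a0) * a0
  if (sqrt(sum(u0^2)) < 1e-9 * max(1, max(abs(P)))) {
    u0 <- P[2L, ] - c0
    u0 <- u0 - sum(u0 * a0) * a0
  }
  u0 <- .unit(u0)
  Rot <- cbind(u0, .cross3(a0, u0), a0)
  Q <- sweep(P, 2L, c0) %*% Rot

  az <- c(0, 0, 1)
  bz <- .perp_basis(az)
  tau0 <- staged$twist * pi / 180
  best <- .helix_conditional(Q, az, tau0)
  if (is.null(best)) stop("degenerate helix fit")

  if (best$rms > 1e-10) {
    objective <- function(par) {
      f <- .helix_conditional(Q, .unit(az + par[1] * bz$u + par[2] * bz$v),
                              par[3])
      if (is.null(f)) Inf else f$rms
    }
    # restarted Nelder-Mead: the fresh simplex of the second pass polishes
    # convergence at negligible cost
    par <- c(0, 0, tau0)
    for (pass in 1:2) {
      opt <- stats::optim(par, objective, method = "Nelder-Mead",
                          control = list(reltol = 1e-13, maxit = 1000))
      par <- opt$par
    }
    cand <- .helix_conditional(Q, .unit(az + par[1] * bz$u + par[2] * bz$v),
                               par[3])
    if (!is.null(cand) && cand$rms < best$rms) best <- cand
  }
  # canonical orientation: rise > 0 (flip both axis and twist if needed)
  if (best$rise < 0) {
    flipped <- .helix_conditional(Q, -best$axis, -best$tau)
    if (!is.null(flipped)) best <- flipped
  }
  list(axis = drop(Rot %*% best$axis),
       axis_point = c0 + drop(Rot %*% (best$cx * best$basis$u +
                                         best$cy * best$basis$v)),
       rise = best$rise,
       twist = best$tau * 180 / pi,
       radius = best$radius,
       rms = best$rms)
}

#' Fit helical parameters to labeled pore-loop points with seam detection
#'
#' Least-squares fit of axis, rise and twist over the protomers in cyclic
#' order, excluding the single protomer whose exclusion minimizes the RMS
#' residual. That protomer is reported as the seam: structurally it is the
#' subunit displaced off the gripping helix, bridging its top and bottom
#' without contacting substrate.
#'
#' @param points A `"pore_loop_set"` (see [gen_pore_loop_helix()]) or a data
#'   frame with columns `protomer`, `loop`, `x`, `y`, `z`. Protomer cyclic
#'   order is taken from the `protomer` column and trusted, not inferred.
#' @param loop Which loop label to fit (required when several are present).
#' @return An object of class `"helix_params"`: list with `axis` (unit
#'   3-vector, oriented so rise > 0), `axis_point`, `rise` (angstrom per
#'   protomer), `twist` (degrees per protomer), `pitch`
#'   (`rise * 360 / twist`, angstrom per turn), `radius`, `rms_residual`,
#'   `seam_index`.
#' @export
fit_helix <- function(points, loop = NULL) {
  if (is.null(loop)) {
    loops <- unique(points$loop)
    if (length(loops) != 1L)
      stop("several loop labels present; specify `loop`")
    loop <- loops
  }
  sel <- points[points$loop == loop, , drop = FALSE]
  sel <- sel[order(sel$protomer), , drop = FALSE]
  n <- nrow(sel)
  if (n < 4L) stop("need >= 4 protomers with the requested loop label")
  P <- .as_xyz(sel)
  prot <- sel$protomer

  fits <- vector("list", n)
  rms <- rep(Inf, n)
  for (s in seq_len(n)) {
    ord <- ((s + seq_len(n - 1L) - 1L) %% n) + 1L  # cyclic order after s
    f <- tryCatch(.helix_ls(P[ord, , drop = FALSE]), error = function(e) NULL)
    if (!is.null(f)) {
      fits[[s]] <- f
      rms[s] <- f$rms
    }
  }
  if (all(!is.finite(rms))) stop("helix fit failed for every seam candidate")
  s_best <- which.min(rms)
  f <- fits[[s_best]]
  structure(list(axis = f$axis, axis_point = f$axis_point,
                 rise = f$rise, twist = f$twist,
                 pitch = f$rise * 360 / f$twist, radius = f$radius,
                 rms_residual = f$rms, seam_index = prot[s_best],
                 loop = loop),
            class = "helix_params")
}

#' @export
print.helix_params <- function(x, ...) {
  cat(sprintf("Helix fit (%s): rise %.3f A, twist %.3f deg, pitch %.2f A\n",
              x$loop, x$rise, x$twist, x$pitch))
  cat(sprintf("  radius %.2f A, rms residual %.3g A, seam protomer %d\n",
              x$radius, x$rms_residual, x$seam_index))
  invisible(x)
}

#' Pore aperture: the widest cylinder passing through a ring of loops
#'
#' Defined as twice the minimum radial distance from the pore axis among the
#' points, i.e. the diameter of the widest axis-centered cylinder that passes
#' through the opening. Reported "across" distances in the literature rarely
#' state their definition; this one is explicit so comparisons are
#' like-with-like (atom-center distances, no van der Waals correction).
#'
#' @param points n x 3 matrix or data frame (x, y, z) of one ring of loops
#'   (>= 3 points).
#' @param axis Unit direction of the pore axis (default z).
#' @param axis_point A point on the axis; defaults to the centroid of
#'   `points`.
#' @return Aperture in the units of the coordinates (angstrom).
#' @export
aperture <- function(points, axis = c(0, 0, 1), axis_point = NULL) {
  P <- .as_xyz(points)
  if (nrow(P) < 3L) stop("need at least 3 points to define an opening")
  a <- .unit(axis)
  c0 <- if (is.null(axis_point)) colMeans(P) else as.numeric(axis_point)
  Q <- sweep(P, 2L, c0)
  axial <- drop(Q %*% a)
  rad <- sqrt(rowSums((Q - outer(axial, a))^2))
  2 * min(rad)
}

#' Tilt of the pore between two rings of loops
#'
#' Angle between the centroid-to-centroid vector of the two rings and the
#' mean of their least-squares plane normals. Coaxial stacked rings give 0; a
#' lateral displacement `d` at axial separation `h` gives `atan(d/h)`.
#'
#' @param ring1,ring2 n x 3 matrices or data frames (x, y, z), >= 3 points
#'   each.
#' @return Tilt angle in degrees, in `[0, 90]`.
#' @export
pore_tilt <- function(ring1, ring2) {
  normal_of <- function(P) {
    Q <- sweep(P, 2L, colMeans(P))
    sv <- svd(Q)
    if (sv$d[2] < 1e-9 * max(1, sv$d[1]))
      stop("degenerate ring: points are collinear, no plane defined")
    sv$v[, 3L]
  }
  P1 <- .as_xyz(ring1); P2 <- .as_xyz(ring2)
  if (nrow(P1) < 3L || nrow(P2) < 3L) stop("each ring needs >= 3 points")
  n1 <- normal_of(P1)
  n2 <- normal_of(P2)
  if (sum(n1 * n2) < 0) n2 <- -n2
  nm <- .unit(n1 + n2)
  cvec <- colMeans(P2) - colMeans(P1)
  if (sqrt(sum(cvec^2)) == 0) stop("ring centroids coincide; tilt undefined")
  cosang <- abs(sum(.unit(cvec) * nm))
  acos(min(1, max(-1, cosang))) * 180 / pi
}

#' Axial extent gripped by the pore loops
#'
#' Length of the projection span of substrate-contact points onto the pore
#' axis (default: the first principal component of the points themselves).
#'
#' @param points n x 3 matrix or data frame (x, y, z) of contact points
#'   (>= 2).
#' @param axis Optional unit axis direction; `NULL` for the principal axis.
#' @return Span in coordinate units (angstrom).
#' @export
grip_extent <- function(points, axis = NULL) {
  P <- .as_xyz(points)
  if (nrow(P) < 2L) stop("need at least 2 contact points")
  a <- if (is.null(axis)) {
    Q <- sweep(P, 2L, colMeans(P))
    svd(Q)$v[, 1L]
  } else .unit(axis)
  diff(range(drop(P %*% a)))
}

#' Predicted first layer line of a helical filament
#'
#' A filament built from stacked helical repeats of pitch `P` shows its first
#' layer line at spatial frequency `1/P`.
#'
#' @param pitch Helical pitch (angstrom), > 0.
#' @return Spatial frequency in 1/angstrom (vectorized).
#' @export
layer_line <- function(pitch) {
  if (any(is.na(pitch) | pitch <= 0)) stop("`pitch` must be positive")
  1 / pitch
}

#' Measure the layer-line frequency of a sampled filament profile
#'
#' Locates the first off-origin maximum of the power spectrum of a density
#' profile sampled along the filament axis: among local maxima of the
#' half-spectrum whose power reaches at least 10% of the strongest off-origin
#' peak, the lowest-frequency one is returned (the floor keeps noise wiggles
#' from masquerading as the layer line). A peak landing in the Nyquist bin
#' cannot be localized and raises an undersampling error.
#'
#' @param profile Numeric vector: density sampled at regular intervals along
#'   the axis (>= 8 samples).
#' @param spacing Sampling interval (angstrom per sample).
#' @return Spatial frequency of the layer line (1/angstrom) with attribute
#'   `bin_width` (the frequency resolution `1/(N * spacing)`).
#' @export
measure_layer_line <- function(profile, spacing = 1) {
  x <- as.numeric(profile)
  N <- length(x)
  if (N < 8L) stop("profile too short: need >= 8 samples")
  if (spacing <= 0) stop("`spacing` must be positive")
  pw <- Mod(stats::fft(x - mean(x)))^2
  half <- pw[2:(N %/% 2 + 1L)]           # bins k = 1 .. N/2
  k <- seq_along(half)
  is_max <- vapply(k, function(i) {
    left <- if (i == 1L) 0 else half[i - 1L]
    right <- if (i == length(half)) 0 else half[i + 1L]
    half[i] > left && half[i] >= right
  }, logical(1))
  cand <- which(is_max & half >= 0.1 * max(half))
  if (length(cand) == 0L)
    stop("no off-origin maximum found; profile may be undersampled")
  kk <- cand[1L]
  if (kk == length(half) && N %% 2L == 0L)
    stop("spectral peak at the Nyquist frequency: profile is undersampled")
  out <- kk / (N * spacing)
  attr(out, "bin_width") <- 1 / (N * spacing)
  out
}
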