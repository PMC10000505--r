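# Bolus ellipsoid geometry: fitting, surface parameterization, antenna frames.

# Overall bounding box of the self-grounded bow-tie element, mm (x: along the
# polarization axis U, y: along V, z: along the pointing axis W).
SGBT_DIMENSIONS <- c(u = 87, v = 62, w = 24)
# Radius of the smallest circle enclosing the antenna on its UV plane, mm.
SGBT_CLEARANCE_RADIUS <- SGBT_DIMENSIONS[["u"]] / 2
# Phase center offset along W from the ground-plate origin, mm.
SGBT_PHASE_CENTER_OFFSET <- 14

#' Axis-aligned bolus ellipsoid
#'
#' @param radii semi-axes (a, b, c) along x/y/z, mm.
#' @param center center, mm.
#' @param trim_offset distance of the caudal cutting plane below the center
#'   (plane perpendicular to z at z = center_z - trim_offset), or `NULL` for an
#'   untrimmed surface.
#' @return object of class `ellipsoid`.
#' @export
ellipsoid <- function(radii, center = c(0, 0, 0), trim_offset = NULL) {
  stopifnot(length(radii) == 3L, all(radii > 0))
  if (!is.null(trim_offset) && trim_offset >= radii[3L]) {
    stop("trim plane does not intersect the ellipsoid")
  }
  structure(list(radii = as.numeric(radii), center = as.numeric(center),
                 trim_offset = if (is.null(trim_offset)) NULL else as.numeric(trim_offset)),
            class = "ellipsoid")
}

#' @export
print.ellipsoid <- function(x, ...) {
  cat(sprintf("Ellipsoid: radii %.1f/%.1f/%.1f mm", x$radii[1], x$radii[2], x$radii[3]))
  if (!is.null(x$trim_offset)) {
    cat(sprintf(", trimmed %.1f mm caudal (extent %.1f mm)",
                x$trim_offset, bolus_extent(x)))
  }
  cat("\n"); invisible(x)
}

#' Cranial-caudal extent of the (possibly trimmed) bolus
#'
#' For a trimmed ellipsoid this is c + trim_offset; untrimmed, 2c.
#' @param e an [ellipsoid()].
#' @export
bolus_extent <- function(e) {
  if (is.null(e$trim_offset)) 2 * e$radii[3L] else e$radii[3L] + e$trim_offset
}

# Maximum colatitude available on a trimmed surface (z >= -trim_offset).
theta_max_of <- function(e) {
  if (is.null(e$trim_offset)) pi else acos(-e$trim_offset / e$radii[3L])
}

#' Surface point of an ellipsoid at spherical surface coordinates
#'
#' Colatitude theta is measured from +z (cranial pole); azimuth phi from +x,
#' right-handed. Vectorized over theta/phi.
#' @param e an [ellipsoid()].
#' @param theta,phi angles in radians.
#' @return n x 3 matrix of mm coordinates.
#' @export
surface_point <- function(e, theta, phi) {
  st <- sin(theta)
  cbind(e$center[1L] + e$radii[1L] * st * cos(phi),
        e$center[2L] + e$radii[2L] * st * sin(phi),
        e$center[3L] + e$radii[3L] * cos(theta))
}

# Inverse parameterization; identity with surface_point away from the poles.
surface_coordinates <- function(e, points) {
  p <- sweep(matrix(points, ncol = 3L), 2L, e$center, "-")
  u <- sweep(p, 2L, e$radii, "/")
  theta <- acos(clamp(u[, 3L] / sqrt(rowSums(u^2)), -1, 1))
  phi <- atan2(u[, 2L], u[, 1L]) %% (2 * pi)
  cbind(theta = theta, phi = phi)
}

# Local surface element |dp/dtheta x dp/dphi| used for uniform-area sampling.
surface_element <- function(e, theta, phi) {
  a <- e$radii[1L]; b <- e$radii[2L]; cc <- e$radii[3L]
  dpt <- cbind(a * cos(theta) * cos(phi), b * cos(theta) * sin(phi), -cc * sin(theta))
  dpp <- cbind(-a * sin(theta) * sin(phi), b * sin(theta) * cos(phi), 0)
  sqrt(rowSums(cross3_rows(dpt, dpp)^2))
}

# Uniform-area random surface coordinates by rejection against the surface
# element factor, restricted to theta <= theta_max.
sample_surface_uniform <- function(e, n, theta_max = theta_max_of(e)) {
  th_probe <- seq(1e-3, theta_max, length.out = 64L)
  ph_probe <- seq(0, 2 * pi, length.out = 64L)
  gmax <- max(surface_element(e, rep(th_probe, each = 64L),
                              rep(ph_probe, times = 64L))) * 1.05
  out_t <- numeric(0); out_p <- numeric(0)
  while (length(out_t) < n) {
    m <- 2L * (n - length(out_t)) + 8L
    th <- stats::runif(m, 0, theta_max)
    ph <- stats::runif(m, 0, 2 * pi)
    keep <- stats::runif(m) < surface_element(e, th, ph) / gmax
    out_t <- c(out_t, th[keep]); out_p <- c(out_p, ph[keep])
  }
  cbind(theta = out_t[seq_len(n)], phi = out_p[seq_len(n)])
}

#' Fit an axis-aligned ellipsoid to a scalp point cloud
#'
#' Points are first offset outward from their centroid by `offset` mm along
#' the radial direction (the bolus stand-off), then an axis-aligned ellipsoid
#' is fitted by minimizing the summed squared algebraic residual of
#' A x^2 + B y^2 + C z^2 + D x + E y + F z = 1.
#'
#' @param scalp_points n x 3 matrix of mm coordinates (n >= 9).
#' @param offset outward offset in mm (default 50, i.e. about 5 cm).
#' @return an [ellipsoid()] with attribute `residual` (RMS algebraic residual).
#' @export
fit_bolus_ellipsoid <- function(scalp_points, offset = 0) {
  p <- as.matrix(scalp_points)
  if (nrow(p) < 9L) stop("need at least 9 points for an ellipsoid fit")
  if (offset != 0) {
    ctr <- colMeans(p)
    d <- sweep(p, 2L, ctr, "-")
    r <- sqrt(rowSums(d^2))
    p <- sweep(d * (1 + offset / pmax(r, 1e-9)), 2L, ctr, "+")
  }
  X <- cbind(p^2, p)
  qrX <- qr(X)
  if (qrX$rank < 6L) stop("degenerate point cloud: ellipsoid fit is rank-deficient")
  beta <- qr.coef(qrX, rep(1, nrow(p)))
  A <- beta[1:3]; B <- beta[4:6]
  if (any(A <= 0)) stop("degenerate point cloud: fitted quadric is not an ellipsoid")
  center <- -B / (2 * A)
  scale <- 1 + sum(B^2 / (4 * A))
  radii <- sqrt(scale / A)
  res <- sqrt(mean((X %*% beta - 1)^2))
  e <- ellipsoid(radii, center)
  attr(e, "residual") <- res
  e
}

#' Antenna pose (local frame) on the bolus surface
#'
#' Builds the antenna's local right-handed orthonormal frame (U, V, W) at the
#' surface point (theta, phi): W points inward along the surface normal, U is
#' tangent to the surface in the plane spanned by the cranial axis z and W
#' (cranially oriented), V = W x U. The origin O is then retracted inward
#' along W by the smallest distance that keeps the antenna back plate's
#' corners inside the water ellipsoid; the phase center O' sits 14 mm further
#' along W.
#'
#' @param e an [ellipsoid()].
#' @param theta,phi surface coordinates, radians.
#' @param retract if `TRUE` (default) apply the back-plate retraction rule.
#' @param antenna_dims bounding box (u, v, w) of the element, mm.
#' @return object of class `antenna_pose` with fields `theta`, `phi`,
#'   `surface_point`, `O`, `O_phase`, `U`, `V`, `W`, `retraction`.
#' @export
antenna_frame <- function(e, theta, phi, retract = TRUE,
                          antenna_dims = SGBT_DIMENSIONS,
                          phase_center_offset = SGBT_PHASE_CENTER_OFFSET) {
  if (!is.null(e$trim_offset) && theta > theta_max_of(e) + 1e-9) {
    stop("pose lies below the trim boundary")
  }
  sp <- drop(surface_point(e, theta, phi))
  # outward normal of ((x-c)/r)^2 sum
  nrm <- (sp - e$center) / e$radii^2
  W <- -unit(nrm)                      # inward
  zhat <- c(0, 0, 1)
  t <- zhat - sum(zhat * W) * W
  if (vnorm(t) < 1e-9) {               # pole: tangent plane is horizontal
    t <- c(1, 0, 0) - sum(c(1, 0, 0) * W) * W
  }
  U <- unit(t)
  if (sum(U * zhat) < 0 && abs(sum(U * zhat)) > 1e-9) U <- -U
  V <- cross3(W, U)
  d <- 0
  if (retract) {
    hu <- antenna_dims[["u"]] / 2; hv <- antenna_dims[["v"]] / 2
    corners <- rbind(hu * U + hv * V, hu * U - hv * V,
                     -hu * U + hv * V, -hu * U - hv * V)
    gfun <- function(dd) {
      pts <- sweep(corners, 2L, sp + dd * W, "+")
      q <- sweep(sweep(pts, 2L, e$center, "-"), 2L, e$radii, "/")
      max(rowSums(q^2)) - 1
    }
    if (gfun(0) > 0) {
      dmax <- min(e$radii) * 0.9
      grid <- seq(0, dmax, by = 1)
      gv <- vapply(grid, gfun, numeric(1))
      k <- which(gv <= 0)[1L]
      if (is.na(k)) stop("antenna cannot be retracted inside the bolus")
      d <- stats::uniroot(gfun, c(grid[k - 1L], grid[k]), tol = 1e-6)$root
    }
  }
  O <- sp + d * W
  structure(list(theta = theta, phi = phi, surface_point = sp, O = O,
                 O_phase = O + phase_center_offset * W,
                 U = U, V = V, W = W, retraction = d,
                 phase_center_offset = phase_center_offset),
            class = "antenna_pose")
}

#' @export
print.antenna_pose <- function(x, ...) {
  cat(sprintf("Antenna pose: theta %.1f deg, phi %.1f deg, retraction %.1f mm\n",
              x$theta * 180 / pi, x$phi * 180 / pi, x$retraction))
  invisible(x)
}

# Rotation matrix mapping frame 1 onto frame 2 (columns U, V, W).
frame_rotation <- function(from, to) {
  B1 <- cbind(from$U, from$V, from$W)
  B2 <- cbind(to$U, to$V, to$W)
  B2 %*% t(B1)
}

#' Feasibility constraints for an antenna arrangement
#'
#' For every unordered antenna pair, the projected-clearance constraint value
#' |L| - l_i - l_j (positive = feasible), where L is the vector between the
#' antenna origins and l is the half-extent of each element's enclosing disc
#' of radius `r` projected along L. For every antenna-eye pair, the chordal
#' distance between the antenna origin and the eye disc center on the bolus
#' surface minus (projected eye radius + r).
#'
#' @param poses list of [antenna_frame()] poses.
#' @param r enclosing-circle radius of the antenna on its UV plane, mm.
#' @param eyes optional list of eye exclusion discs, each a list with
#'   `center` (mm, on the bolus surface) and `radius` (mm).
#' @return list with `pair` (symmetric matrix of constraint values, mm) and
#'   `eye` (n_poses x n_eyes matrix), plus `feasible` (all values > 0).
#' @export
clearance_constraints <- function(poses, r = SGBT_CLEARANCE_RADIUS, eyes = NULL) {
  n <- length(poses)
  pair <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      L <- poses[[i]]$O - poses[[j]]$O
      nl <- vnorm(L)
      if (nl < .Machine$double.eps) {
        pair[i, j] <- -2 * r
        next
      }
      Lh <- L / nl
      li <- sqrt((r * sum(poses[[i]]$U * Lh))^2 + (r * sum(poses[[i]]$V * Lh))^2)
      lj <- sqrt((r * sum(poses[[j]]$U * Lh))^2 + (r * sum(poses[[j]]$V * Lh))^2)
      pair[i, j] <- nl - li - lj
    }
  }
  eye_mat <- NULL
  if (!is.null(eyes) && length(eyes)) {
    eye_mat <- matrix(NA_real_, n, length(eyes))
    for (i in seq_len(n)) {
      for (k in seq_along(eyes)) {
        eye_mat[i, k] <- vnorm(poses[[i]]$O - eyes[[k]]$center) -
          (eyes[[k]]$radius + r)
      }
    }
  }
  vals <- c(pair[upper.tri(pair)], eye_mat)
  list(pair = pair, eye = eye_mat,
       feasible = all(vals > 0, na.rm = TRUE))
}

#' Project an eye onto the bolus surface as an exclusion disc
#'
#' The eye center is projected radially (from the ellipsoid center) onto the
#' surface; the disc radius is the eye radius plus the antenna clearance
#' radius applied by [clearance_constraints()] through its `r` argument.
#' @param e bolus [ellipsoid()].
#' @param eye_center,eye_radius eye sphere in mm.
#' @export
project_eye_disc <- function(e, eye_center, eye_radius) {
  co <- surface_coordinates(e, matrix(eye_center, 1L))
  ctr <- drop(surface_point(e, co[1L, 1L], co[1L, 2L]))
  list(center = ctr, radius = eye_radius)
}
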