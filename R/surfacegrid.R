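# Surface interpolation grid: charged-particle spreading, spherical Delaunay
# triangulation (via the 3-D convex hull of the sphere-mapped nodes), patch
# location with area-ratio weights.

# --- incremental 3-D convex hull -------------------------------------------
# Points must be in general position on a convex surface (unit sphere here),
# so every point is a hull vertex. Returns an f x 3 matrix of vertex indices
# with outward-oriented faces.
convex_hull3 <- function(pts, tol = 1e-10) {
  n <- nrow(pts)
  if (n < 4L) stop("need at least 4 points for a 3-D hull")
  # initial non-degenerate tetrahedron
  i1 <- which.min(pts[, 1L])
  d1 <- rowSums(sweep(pts, 2L, pts[i1, ], "-")^2)
  i2 <- which.max(d1)
  e1 <- pts[i2, ] - pts[i1, ]
  a <- sweep(pts, 2L, pts[i1, ], "-")
  cr <- cross3_rows(a, matrix(e1, n, 3L, byrow = TRUE))
  i3 <- which.max(rowSums(cr^2))
  nrm <- cross3(e1, pts[i3, ] - pts[i1, ])
  h <- abs(a %*% nrm)
  i4 <- which.max(h)
  if (h[i4] < tol) stop("degenerate (coplanar) point set")
  faces <- rbind(c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4), c(i2, i3, i4))
  ctr <- colMeans(pts[c(i1, i2, i3, i4), ])
  orient <- function(f) {
    nn <- cross3(pts[f[2L], ] - pts[f[1L], ], pts[f[3L], ] - pts[f[1L], ])
    if (sum(nn * (pts[f[1L], ] - ctr)) < 0) f[c(1L, 3L, 2L)] else f
  }
  faces <- t(apply(faces, 1L, orient))
  rest <- setdiff(seq_len(n), c(i1, i2, i3, i4))
  for (p in rest) {
    fn <- t(apply(faces, 1L, function(f) {
      cross3(pts[f[2L], ] - pts[f[1L], ], pts[f[3L], ] - pts[f[1L], ])
    }))
    vis <- rowSums(fn * (matrix(pts[p, ], nrow(faces), 3L, byrow = TRUE) -
                           pts[faces[, 1L], , drop = FALSE])) > tol
    if (!any(vis)) next  # inside current hull (should not happen on a sphere)
    # horizon = edges bordering exactly one visible face
    edges_of <- function(f) rbind(f[c(1L, 2L)], f[c(2L, 3L)], f[c(3L, 1L)])
    vis_edges <- do.call(rbind, lapply(which(vis), function(r) edges_of(faces[r, ])))
    keys <- paste(pmin(vis_edges[, 1L], vis_edges[, 2L]),
                  pmax(vis_edges[, 1L], vis_edges[, 2L]))
    horizon <- vis_edges[keys %in% names(which(table(keys) == 1L)), , drop = FALSE]
    faces <- faces[!vis, , drop = FALSE]
    new_faces <- cbind(horizon, p)
    new_faces <- t(apply(new_faces, 1L, orient))
    faces <- rbind(faces, new_faces)
  }
  dimnames(faces) <- NULL
  faces
}

# --- repulsion objective ----------------------------------------------------
# x = c(theta_1..n, phi_1..n); returns sum over pairs of 1/d^2 (chordal mm)
# and its analytic gradient.
repulsion_objective <- function(x, e, n) {
  th <- x[seq_len(n)]; ph <- x[n + seq_len(n)]
  P <- surface_point(e, th, ph)
  dx <- outer(P[, 1L], P[, 1L], "-")
  dy <- outer(P[, 2L], P[, 2L], "-")
  dz <- outer(P[, 3L], P[, 3L], "-")
  d2 <- dx^2 + dy^2 + dz^2
  diag(d2) <- Inf
  f <- sum(1 / d2) / 2
  # dF/dP_i = sum_j -2 (P_i - P_j) / d^4
  inv4 <- 1 / d2^2
  gx <- -2 * rowSums(dx * inv4)
  gy <- -2 * rowSums(dy * inv4)
  gz <- -2 * rowSums(dz * inv4)
  a <- e$radii[1L]; b <- e$radii[2L]; cc <- e$radii[3L]
  st <- sin(th); ct <- cos(th); sp <- sin(ph); cp <- cos(ph)
  gth <- gx * a * ct * cp + gy * b * ct * sp - gz * cc * st
  gph <- -gx * a * st * sp + gy * b * st * cp
  list(value = f, gradient = c(gth, gph))
}

#' Spread antenna grid points over the bolus surface by mutual repulsion
#'
#' Places `n_points` nodes on the (possibly trimmed) ellipsoid surface by
#' minimizing the sum of inverse squared chordal distances between all pairs
#' (the electrostatic repulsion analogy), starting from a uniform-area random
#' configuration and keeping the best of `n_starts` seeded local
#' minimizations. Nodes are then triangulated by mapping them to the unit
#' sphere and taking the convex hull (spherical Delaunay); triangles covering
#' the trimmed caudal opening are discarded. Edge statistics (chordal mm) are
#' recorded.
#'
#' @param e bolus [ellipsoid()].
#' @param n_points number of grid nodes (>= 4).
#' @param theta_max colatitude bound; defaults to the trim ring of `e`.
#' @param seed integer seed (deterministic output).
#' @param n_starts number of random multi-starts (default 8).
#' @param maxit L-BFGS-B iteration cap per start.
#' @return object of class `surface_grid`: `theta`, `phi`, `triangles`
#'   (t x 3 index matrix), `edges`, `max_edge`, `mean_edge`, `ellipsoid`,
#'   `objective`.
#' @export
spread_surface_grid <- function(e, n_points, theta_max = NULL, seed = 1L,
                                n_starts = 8L, maxit = 400L) {
  if (n_points < 2L) stop("need at least 2 points")
  thmax <- theta_max %||% theta_max_of(e)
  if (thmax <= 1e-3) stop("infeasible theta_max: empty surface region")
  seeds <- child_seeds(seed, n_starts)
  best <- NULL
  for (s in seq_len(n_starts)) {
    set.seed(seeds[s])
    start <- sample_surface_uniform(e, n_points, thmax)
    x0 <- c(start[, 1L], start[, 2L])
    fit <- stats::optim(
      x0,
      fn = function(x) repulsion_objective(x, e, n_points)$value,
      gr = function(x) repulsion_objective(x, e, n_points)$gradient,
      method = "L-BFGS-B",
      lower = c(rep(1e-3, n_points), rep(-Inf, n_points)),
      upper = c(rep(thmax, n_points), rep(Inf, n_points)),
      control = list(maxit = maxit, factr = 1e4))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  th <- best$par[seq_len(n_points)]
  ph <- best$par[n_points + seq_len(n_points)] %% (2 * pi)
  grid <- structure(list(theta = th, phi = ph, ellipsoid = e,
                         theta_max = thmax, objective = best$value),
                    class = "surface_grid")
  if (n_points >= 4L) {
    grid <- triangulate_grid(grid)
  } else {
    grid$triangles <- matrix(integer(0), 0L, 3L)
    P <- surface_point(e, th, ph)
    dd <- as.matrix(stats::dist(P))
    grid$edges <- which(upper.tri(dd), arr.ind = TRUE)
    grid$edge_lengths <- dd[upper.tri(dd)]
    grid$max_edge <- max(grid$edge_lengths)
    grid$mean_edge <- mean(grid$edge_lengths)
  }
  grid
}

# Triangulate grid nodes: unit-sphere map -> convex hull -> drop cap faces.
triangulate_grid <- function(grid) {
  e <- grid$ellipsoid
  u <- cbind(sin(grid$theta) * cos(grid$phi),
             sin(grid$theta) * sin(grid$phi),
             cos(grid$theta))
  tri <- convex_hull3(u)
  if (grid$theta_max < pi - 1e-6) {
    # faces whose vertices all hug the trim ring close over the caudal
    # opening; drop them
    on_ring <- grid$theta[tri] > grid$theta_max - 1e-3
    dim(on_ring) <- dim(tri)
    keep <- rowSums(on_ring) < 3L
    tri <- tri[keep, , drop = FALSE]
  }
  P <- surface_point(e, grid$theta, grid$phi)
  ed <- rbind(tri[, c(1L, 2L)], tri[, c(2L, 3L)], tri[, c(3L, 1L)])
  ed <- cbind(pmin(ed[, 1L], ed[, 2L]), pmax(ed[, 1L], ed[, 2L]))
  ed <- unique(ed)
  len <- sqrt(rowSums((P[ed[, 1L], , drop = FALSE] - P[ed[, 2L], , drop = FALSE])^2))
  grid$triangles <- tri
  grid$edges <- ed
  grid$edge_lengths <- len
  grid$max_edge <- max(len)
  grid$mean_edge <- mean(len)
  grid$points <- P
  grid
}

#' @export
print.surface_grid <- function(x, ...) {
  cat(sprintf("Surface grid: %d nodes, %d triangles, max edge %.1f mm, mean edge %.1f mm\n",
              length(x$theta), nrow(x$triangles %||% matrix(0, 0, 3)),
              x$max_edge, x$mean_edge))
  invisible(x)
}

#' Find the grid size achieving a target sampling distance
#'
#' Repeats the repulsion spreading for increasing `n_points` until the
#' maximum triangulation-edge length falls below `target_edge` mm.
#'
#' @param e bolus [ellipsoid()].
#' @param target_edge target maximum nearby-pair distance, mm.
#' @param seed integer seed.
#' @param n_start,n_max search range; n grows by `growth` each step.
#' @param ... passed to [spread_surface_grid()] (e.g. faster `n_starts`).
#' @return list with `n_points` and the final `grid`.
#' @export
size_search <- function(e, target_edge, seed = 1L, n_start = 20L, n_max = 600L,
                        growth = 1.25, ...) {
  n <- n_start
  repeat {
    grid <- spread_surface_grid(e, n, seed = seed, ...)
    if (grid$max_edge <= target_edge || n >= n_max) {
      return(list(n_points = n, grid = grid))
    }
    n <- min(n_max, ceiling(n * growth))
  }
}

#' Locate the interpolation patch of a query pose
#'
#' Finds the triangle of the grid containing the surface direction
#' (theta, phi) and returns area-ratio barycentric weights computed from the
#' cross-product areas of the sub-triangles spanned by the query surface
#' point and the patch corners. At a node the weights are (1, 0, 0); queries
#' outside the covered region are clamped to the nearest patch and flagged.
#'
#' @param grid a [spread_surface_grid()] result.
#' @param theta,phi query surface coordinates, radians.
#' @return list with `nodes` (indices of the patch corners), `weights`
#'   (nonnegative, summing to 1) and `clamped`.
#' @export
locate_patch <- function(grid, theta, phi) {
  if (is.null(grid$triangles) || nrow(grid$triangles) == 0L) {
    stop("grid has no triangulation")
  }
  uq <- c(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
  u <- cbind(sin(grid$theta) * cos(grid$phi),
             sin(grid$theta) * sin(grid$phi),
             cos(grid$theta))
  tri <- grid$triangles
  nt <- nrow(tri)
  inside <- -Inf; best <- NA_integer_
  for (t in seq_len(nt)) {
    M <- t(u[tri[t, ], ])
    cf <- tryCatch(solve(M, uq), error = function(err) NULL)
    if (is.null(cf)) next
    score <- min(cf)
    if (score > inside) { inside <- score; best <- t }
    if (score >= -1e-12) break
  }
  if (is.na(best)) stop("degenerate triangulation")
  clamped <- inside < -1e-12
  nodes <- tri[best, ]
  Pq <- drop(surface_point(grid$ellipsoid, theta, phi))
  P <- grid$points[nodes, , drop = FALSE]
  area2 <- function(a, b, cpt) vnorm(cross3(b - a, cpt - a))
  w <- c(area2(Pq, P[2L, ], P[3L, ]),
         area2(P[1L, ], Pq, P[3L, ]),
         area2(P[1L, ], P[2L, ], Pq))
  total <- area2(P[1L, ], P[2L, ], P[3L, ])
  if (total < 1e-12) stop("zero-area interpolation patch")
  # exact hit on a node
  dq <- sqrt(rowSums(sweep(P, 2L, Pq, "-")^2))
  if (min(dq) < 1e-9) {
    w <- as.numeric(dq < 1e-9)
  }
  if (clamped) {
    # clamp: project out negative gnomonic coordinates, renormalize areas
    M <- t(u[nodes, ])
    cf <- solve(M, uq)
    w[cf < 0] <- 0
  }
  w <- w / sum(w)
  list(nodes = nodes, weights = w, clamped = clamped)
}
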