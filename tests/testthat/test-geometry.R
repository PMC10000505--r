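test_that("ellipsoid fit recovers the generating surface", {
  e0 <- ellipsoid(c(125, 142, 144))
  set.seed(3)
  co <- helmetplan:::sample_surface_uniform(e0, 300)
  pts <- surface_point(e0, co[, 1], co[, 2])
  fit <- fit_bolus_ellipsoid(pts)
  expect_lt(max(abs(fit$radii - c(125, 142, 144)) / c(125, 142, 144)), 0.01)
  # sphere -> equal radii
  es <- ellipsoid(c(90, 90, 90))
  co <- helmetplan:::sample_surface_uniform(es, 200)
  fs <- fit_bolus_ellipsoid(surface_point(es, co[, 1], co[, 2]))
  expect_equal(fs$radii, rep(90, 3), tolerance = 1e-6)
  # noisy sphere: sigma = 1 mm, n = 500
  set.seed(8)
  co <- helmetplan:::sample_surface_uniform(es, 500)
  noisy <- surface_point(es, co[, 1], co[, 2]) + matrix(rnorm(1500), ncol = 3)
  fn <- fit_bolus_ellipsoid(noisy)
  expect_lt(max(abs(fn$radii - 90) / 90), 0.02)
  # offsetting moves the surface outward radially
  fo <- fit_bolus_ellipsoid(surface_point(es, co[, 1], co[, 2]), offset = 50)
  expect_equal(fo$radii, rep(140, 3), tolerance = 1e-3)
  # coplanar cloud is degenerate
  flat <- cbind(runif(20), runif(20), 0)
  expect_error(fit_bolus_ellipsoid(flat), "degenerate")
  expect_error(fit_bolus_ellipsoid(pts[1:5, ]), "at least 9")
})

test_that("antenna frames are orthonormal, inward, cranially aligned", {
  e <- ellipsoid(c(125, 142, 144), trim_offset = 77)
  # equatorial pose sits at (a, 0, 0)
  fr <- antenna_frame(e, pi / 2, 0, retract = FALSE)
  expect_equal(fr$surface_point, c(125, 0, 0), tolerance = 1e-9)
  expect_equal(fr$W, c(-1, 0, 0), tolerance = 1e-9)
  # pole: W = (0, 0, -1)
  sp <- ellipsoid(rep(100, 3))
  fp <- antenna_frame(sp, 0, 0, retract = FALSE)
  expect_equal(fp$surface_point, c(0, 0, 100), tolerance = 1e-9)
  expect_equal(fp$W, c(0, 0, -1), tolerance = 1e-9)
  set.seed(4)
  for (i in 1:10) {
    th <- runif(1, 0.1, theta_max_of(e) - 0.05); ph <- runif(1, 0, 2 * pi)
    f <- antenna_frame(e, th, ph)
    B <- cbind(f$U, f$V, f$W)
    expect_equal(t(B) %*% B, diag(3), tolerance = 1e-9)
    expect_equal(det(B), 1, tolerance = 1e-9)
    # U lies in the plane spanned by z and W
    expect_equal(abs(sum(f$U * helmetplan:::cross3(c(0, 0, 1), f$W))), 0,
                 tolerance = 1e-9)
    # retraction keeps O inside the bolus
    q <- sum(((f$O - e$center) / e$radii)^2)
    expect_lte(q, 1 + 1e-9)
    # phase center 14 mm further inward
    expect_equal(f$O_phase, f$O + 14 * f$W)
  }
  expect_error(antenna_frame(e, theta_max_of(e) + 0.2, 0), "trim")
})

test_that("repulsion spreading attains known optima and is deterministic", {
  sp <- ellipsoid(rep(100, 3))
  # n = 2: antipodal points
  g2 <- spread_surface_grid(sp, 2, seed = 1, n_starts = 4, maxit = 200)
  P2 <- surface_point(sp, g2$theta, g2$phi)
  expect_equal(sqrt(sum((P2[1, ] - P2[2, ])^2)), 200, tolerance = 1e-3)
  # n = 4: regular tetrahedron, pairwise distance sqrt(8/3) R
  g4 <- spread_surface_grid(sp, 4, seed = 3, n_starts = 4, maxit = 300)
  P4 <- surface_point(sp, g4$theta, g4$phi)
  d <- as.matrix(dist(P4)); d <- d[upper.tri(d)]
  expect_equal(d, rep(sqrt(8 / 3) * 100, 6), tolerance = 1e-3)
  # determinism
  g4b <- spread_surface_grid(sp, 4, seed = 3, n_starts = 4, maxit = 300)
  expect_identical(g4$theta, g4b$theta)
  expect_error(spread_surface_grid(sp, 8, theta_max = 1e-5), "infeasible")
})

test_that("study-ellipsoid grid statistics shrink with grid size", {
  e <- ellipsoid(c(125, 142, 144), trim_offset = 77)
  expect_equal(bolus_extent(e) / 10, 22.1, tolerance = 1e-9)
  stats <- vapply(c(50L, 100L, 221L), function(np) {
    g1 <- spread_surface_grid(e, np, seed = 1, n_starts = 2, maxit = 250)
    g2 <- spread_surface_grid(e, np, seed = 2, n_starts = 2, maxit = 250)
    c(max = mean(c(g1$max_edge, g2$max_edge)),
      mean = mean(c(g1$mean_edge, g2$mean_edge)))
  }, numeric(2))
  expect_true(all(diff(stats["max", ]) < 0))
  expect_true(all(diff(stats["mean", ]) < 0))
  # parameterization round trip away from poles
  co <- cbind(runif(20, 0.2, 2), runif(20, 0, 2 * pi))
  pts <- surface_point(e, co[, 1], co[, 2])
  back <- helmetplan:::surface_coordinates(e, pts)
  expect_equal(back[, "theta"], co[, 1], tolerance = 1e-9)
  expect_equal(back[, "phi"], co[, 2], tolerance = 1e-9)
})

test_that("size search grows the grid until the target edge is met", {
  sp <- ellipsoid(rep(100, 3))
  res <- size_search(sp, target_edge = 85, seed = 2, n_start = 12,
                     n_max = 80, n_starts = 2, maxit = 150)
  expect_lte(res$grid$max_edge, 85)
  # a sparser grid than the solution cannot meet the target
  coarse <- spread_surface_grid(sp, max(4L, res$n_points %/% 2L), seed = 2,
                                n_starts = 2, maxit = 150)
  expect_gt(coarse$max_edge, 85)
  # JSON round trip preserves the triangulated grid
  tf <- tempfile(fileext = ".json")
  write_surface_grid(res$grid, tf)
  back <- read_surface_grid(tf)
  expect_equal(back$theta, res$grid$theta, tolerance = 1e-12)
  expect_equal(back$max_edge, res$grid$max_edge, tolerance = 1e-9)
  expect_equal(dim(back$triangles), dim(res$grid$triangles))
})

test_that("patch location returns area-ratio weights", {
  sp <- ellipsoid(rep(100, 3))
  g <- spread_surface_grid(sp, 16, seed = 5, n_starts = 2, maxit = 200)
  # query at a node
  lp <- locate_patch(g, g$theta[3], g$phi[3])
  expect_true(3 %in% lp$nodes)
  expect_equal(lp$weights[lp$nodes == 3], 1)
  expect_equal(sum(lp$weights), 1)
  # centroid of a symmetric patch on the sphere: equal weights
  tr <- g$triangles[1, ]
  u <- cbind(sin(g$theta) * cos(g$phi), sin(g$theta) * sin(g$phi), cos(g$theta))
  d <- colMeans(u[tr, ]); d <- d / sqrt(sum(d^2))
  lc <- locate_patch(g, acos(d[3]), atan2(d[2], d[1]) %% (2 * pi))
  expect_setequal(lc$nodes, tr)
  # weights against an independent gnomonic solve (convex reconstruction)
  set.seed(6)
  for (i in 1:5) {
    tr <- g$triangles[sample(nrow(g$triangles), 1), ]
    w0 <- runif(3); w0 <- w0 / sum(w0)
    q <- drop(w0 %*% g$points[tr, ])  # planar point inside the patch
    co <- helmetplan:::surface_coordinates(sp, matrix(q, 1))
    lp <- locate_patch(g, co[1, 1], co[1, 2])
    expect_setequal(lp$nodes, tr)
    expect_gte(min(lp$weights), -1e-12)
    expect_equal(sum(lp$weights), 1)
    # cross-product area oracle on the surface query point
    Pq <- drop(surface_point(sp, co[1, 1], co[1, 2]))
    P <- g$points[lp$nodes, ]
    a2 <- function(a, b, cc) {
      v <- helmetplan:::cross3(b - a, cc - a); sqrt(sum(v^2))
    }
    wo <- c(a2(Pq, P[2, ], P[3, ]), a2(P[1, ], Pq, P[3, ]),
            a2(P[1, ], P[2, ], Pq))
    expect_equal(lp$weights, wo / sum(wo), tolerance = 1e-9)
  }
})

test_that("clearance constraints are symmetric and sign-correct", {
  e <- ellipsoid(c(125, 142, 144), trim_offset = 77)
  pa <- antenna_frame(e, 1.2, 0.4)
  pb <- antenna_frame(e, 1.2, 0.4)
  co <- clearance_constraints(list(pa, pb))
  expect_lt(co$pair[1, 2], 0)   # coincident: infeasible
  pc <- antenna_frame(e, 1.2, 0.4 + pi)
  far <- clearance_constraints(list(pa, pc))
  expect_gt(far$pair[1, 2], 0)  # antipodal: feasible
  set.seed(9)
  for (i in 1:5) {
    p1 <- antenna_frame(e, runif(1, 0.2, 2), runif(1, 0, 2 * pi))
    p2 <- antenna_frame(e, runif(1, 0.2, 2), runif(1, 0, 2 * pi))
    cc <- clearance_constraints(list(p1, p2))
    expect_equal(cc$pair[1, 2], cc$pair[2, 1])
  }
  # eye exclusion disc blocks nearby poses
  eye <- project_eye_disc(e, c(40, 120, 5), 12)
  co_eye <- helmetplan:::surface_coordinates(e, matrix(eye$center, 1))
  blocked <- antenna_frame(e, co_eye[1, 1], co_eye[1, 2])
  cb <- clearance_constraints(list(blocked), eyes = list(eye))
  expect_lt(cb$eye[1, 1], 0)
})
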