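test_that("polarization projection extracts the co-polarized drive", {
  dm <- c(9, 9, 9)
  p <- make_pose(c(0, 0, -14), c(0, 1, 0), c(0, 0, 1), c(1, 0, 0))
  # O_phase = O + 14 W = origin; U = y
  EU <- const_field(dm, c(0, 1, 0))
  expect_equal(project_coupling_drive(EU, p), 1 + 0i)
  Ev <- const_field(dm, c(1, 0, 0))
  expect_equal(project_coupling_drive(Ev, p), 0 + 0i)
  # (1+j) U + 3 V: the V component is discarded
  Em <- const_field(dm, c(0, 1 + 1i, 3))
  expect_equal(project_coupling_drive(Em, p), 1 + 1i)
  pout <- make_pose(c(1000, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 0, 0))
  expect_error(project_coupling_drive(EU, pout), "outside")
})

test_that("decorrelation solves the least-squares remainder fit", {
  dm <- c(7, 7, 7)
  set.seed(21)
  rnd <- function() {
    E <- const_field(dm, c(0, 0, 0))
    E[] <- complex(real = rnorm(length(E)), imaginary = rnorm(length(E)))
    E
  }
  EA <- rnd(); EP <- rnd()
  k0 <- 0.3 - 0.1i
  expect_equal(estimate_k_by_decorrelation(EA, EP, EA + k0 * EP), k0,
               tolerance = 1e-12)
  # remainder orthogonal to EP over M gives zero
  EAP <- EA + 0 * EP
  expect_equal(estimate_k_by_decorrelation(EA, EP, EAP), 0 + 0i)
  expect_error(estimate_k_by_decorrelation(EA, 0 * EP, EAP), "zero energy")
})

test_that("coupling coefficient fit is exact on constructed pairs", {
  set.seed(31)
  e <- complex(real = rnorm(30), imaginary = rnorm(30))
  c0 <- 0.04 - 0.03i
  fit <- fit_coupling_coefficient(e, c0 * e, f = 500e6)
  expect_equal(fit$c, c0, tolerance = 1e-12)
  expect_equal(fit$correlation, 1, tolerance = 1e-9)
  # a single pair duplicated gives c = k / e
  fit1 <- fit_coupling_coefficient(rep(e[1], 2), rep(c0 * e[1] * 1.5, 2))
  expect_equal(fit1$c, 1.5 * c0, tolerance = 1e-12)
  expect_error(fit_coupling_coefficient(complex(3), complex(3)), "zero")
  # serialization round trip
  tf <- tempfile(fileext = ".json")
  write_coupling_model(fit, tf)
  back <- read_coupling_model(tf)
  expect_equal(back$c, fit$c)
  expect_equal(back$K, fit$K)
})

test_that("array coupling correction follows the matrix-power expansion", {
  dm <- c(9, 9, 9)
  set.seed(41)
  mk <- function() {
    E <- const_field(dm, c(0, 0, 0))
    E[] <- complex(real = rnorm(length(E)), imaginary = rnorm(length(E)))
    E
  }
  E1 <- mk(); E2 <- mk()
  p1 <- make_pose(c(-10, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 0, 0))
  p2 <- make_pose(c(24, 0, 0), c(0, 0, 1), c(0, -1, 0), c(-1, 0, 0))
  cm <- structure(list(c = 0.05 + 0.01i, K = 3L), class = "coupling_model")
  # K = 1: identity
  out1 <- apply_array_coupling(list(E1, E2), list(p1, p2), cm, K = 1)
  expect_identical(out1[[1]], E1)
  # c = 0: identity for any K
  cm0 <- structure(list(c = 0 + 0i, K = 3L), class = "coupling_model")
  out0 <- apply_array_coupling(list(E1, E2), list(p1, p2), cm0, K = 4)
  expect_equal(out0[[1]][, , , ], E1[, , , ], tolerance = 1e-14)
  # K = 2, two channels: hand-expanded product
  e12 <- project_coupling_drive(E1, p2)
  e21 <- project_coupling_drive(E2, p1)
  out2 <- apply_array_coupling(list(E1, E2), list(p1, p2), cm, K = 2)
  expect_equal(out2[[1]][, , , ], (E1 + cm$c * e12 * E2)[, , , ], tolerance = 1e-12)
  expect_equal(out2[[2]][, , , ], (E2 + cm$c * e21 * E1)[, , , ], tolerance = 1e-12)
  # Neumann consistency: successive K differ geometrically when |c e| < 1
  d32 <- {
    o3 <- apply_array_coupling(list(E1, E2), list(p1, p2), cm, K = 3)
    sqrt(sum(Mod(o3[[1]] - out2[[1]])^2))
  }
  d21 <- sqrt(sum(Mod(out2[[1]] - E1)^2))
  expect_lt(d32 / d21, Mod(cm$c) * max(Mod(e12), Mod(e21)) * 1.5)
  expect_error(apply_array_coupling(list(E1, E2), list(p1), cm), "mismatch")
})

test_that("coupling is reciprocal in a symmetric geometry", {
  mod <- fx_sphere()
  e <- fx_pose_sphere()
  a <- antenna_frame(e, pi / 2, 0, retract = FALSE)
  p <- antenna_frame(e, pi / 2, pi, retract = FALSE)
  c_true <- 0.05 + 0.02i
  pe1 <- oracle_pair_experiment(mod, a, p, 500e6, c_true)
  pe2 <- oracle_pair_experiment(mod, p, a, 500e6, c_true)
  k12 <- estimate_k_by_decorrelation(pe1$EA, pe1$EP, pe1$EAP)
  k21 <- estimate_k_by_decorrelation(pe2$EA, pe2$EP, pe2$EAP)
  expect_equal(k12, k21, tolerance = 1e-3)
})

test_that("fitted coupling reduces the field error of oracle arrays", {
  # ground truth: pairwise first-reflection synthesis with known c;
  # approximation: individual fields + fitted correction at K = 2 and 3
  mod <- fx_sphere()
  e <- fx_pose_sphere()
  c_true <- 0.08 + 0.03i
  a <- antenna_frame(e, 1.0, 0.7, retract = FALSE)
  p <- antenna_frame(e, 1.3, 2.2, retract = FALSE)
  pe <- oracle_pair_experiment(mod, a, p, 500e6, c_true)
  cm <- calibrate_coupling(mod, e, 500e6, c_true, n_pairs = 6, seed = 13)
  pm <- helmetplan:::patient_mask(mod)
  err_of <- function(E) {
    field_error_metrics(pe$EAP, E, pm, a$U, mod, mass_average = FALSE)$dis
  }
  uncorrected <- err_of(pe$EA)
  for (K in 2:3) {
    corr <- apply_array_coupling(list(pe$EA, pe$EP), list(a, p), cm, K = K)
    expect_lt(err_of(corr[[1]]), uncorrected)
  }
})
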