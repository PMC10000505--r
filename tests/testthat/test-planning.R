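test_that("SAR assembly is coherent in channels, incoherent in frequency", {
  mod <- fx_sphere_tumor()
  e <- fx_pose_sphere()
  f <- 500e6
  pose <- antenna_frame(e, 1.0, 0.5, retract = FALSE)
  E <- oracle_antenna_field(mod, pose, f)
  pr <- lookup_properties(mod, f)
  n <- prod(dim(mod$labels))
  # single channel: SAR = sigma |E|^2 / (2 rho)
  sar <- assemble_sar(list(list(E)), matrix(1 + 0i), mod, f)
  e2 <- Mod(E[seq_len(n)])^2 + Mod(E[n + seq_len(n)])^2 + Mod(E[2 * n + seq_len(n)])^2
  expect_equal(as.vector(sar), 0.5 * as.vector(pr$sigma) / as.vector(pr$rho) * e2,
               tolerance = 1e-12)
  expect_true(all(sar[mod$labels == 0L] == 0))  # zero where sigma = 0
  # quadratic scaling
  sar2 <- assemble_sar(list(list(E)), matrix(2 + 0i), mod, f)
  expect_equal(sar2, 4 * sar, tolerance = 1e-12)
  # destructive interference of equal channels
  sar0 <- assemble_sar(list(list(E, E)), matrix(c(1 + 0i, -1 + 0i), 1), mod, f)
  expect_equal(max(sar0), 0)
  expect_error(assemble_sar(list(list(E, E)), matrix(1 + 0i), mod, f),
               "channel")
})

test_that("5 g mass averaging respects kernel mass book-keeping", {
  # uniform density block at 4 mm: voxel mass 0.064 g, 5x5x5 kernel = 8 g
  dm <- c(21, 21, 21)
  rho <- array(1000, dm)
  mask <- array(TRUE, dm)
  sar <- array(1, dm)
  avg <- mass_average_5g(sar, rho, mask, spacing = rep(4, 3))
  expect_equal(avg[11, 11, 11], 1, tolerance = 1e-12)  # interior unchanged
  # single-voxel spike spreads over the kernel: peak = voxel/kernel mass
  spike <- array(0, dm); spike[11, 11, 11] <- 1
  avg_s <- mass_average_5g(spike, rho, mask, spacing = rep(4, 3))
  expect_equal(avg_s[11, 11, 11], 0.064 / 8, tolerance = 1e-12)
  # surface voxels: kernel mass lands in [5 g, 5 g + one shell]
  kr <- helmetplan:::kernel_radius_map(rho, mask, rep(4, 3))
  corner_r <- kr$rmap[1, 1, 1]
  m_corner <- helmetplan:::box_sum(kr$mvol, corner_r)[1, 1, 1]
  m_prev <- if (corner_r > 0) helmetplan:::box_sum(kr$mvol, corner_r - 1L)[1, 1, 1] else 0
  expect_gte(m_corner, 0.005)
  expect_lt(m_prev, 0.005)
  expect_error(mass_average_5g(sar, array(1, dm), mask, rep(1, 3)), "mass")
})

test_that("evaluation masks satisfy the percentile coupling relation", {
  mod <- fx_sphere_tumor()
  masks <- build_evaluation_masks(mod, p = 50, exclusion_mm = 20)
  # q = p |T| / |R| holds exactly by construction
  expect_equal(masks$q * sum(masks$remaining), masks$p * sum(masks$target),
               tolerance = 1e-9)
  expect_true(!any(masks$target & masks$remaining))
  # printed-style arithmetic: 126 mL target over 2250 mL remaining at p = 50
  expect_equal(50 * 126 / 2250, 2.8)
  # excluded rind: no remaining voxel within 20 mm of water/air
  pm <- helmetplan:::patient_mask(mod)
  depth <- helmetplan:::distance_transform(!pm, mod$spacing)
  expect_true(all(depth[masks$remaining] > 20))
  # brute-force voxel-count oracle for q
  expect_equal(masks$q, masks$p * sum(masks$target) / sum(masks$remaining))
  expect_error(build_evaluation_masks(fx_sphere(), p = 50), "target")
})

test_that("HCQ matches brute-force tail means and is scale invariant", {
  # 8-voxel toy: explicit enumeration
  dm <- c(2, 2, 2)
  sar <- array(c(4, 1, 3, 2, 10, 30, 20, 40), dm)
  masks <- structure(list(
    target = array(c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE), dm),
    remaining = array(c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE), dm),
    p = 50, q = 50), class = "mask_set")
  got <- hcq(sar, masks)
  # lowest 50% of {1,2,3,4} -> mean(1,2); highest 50% of {10,20,30,40} -> mean(40,30)
  expect_equal(got$sar_target_low, 1.5)
  expect_equal(got$sar_remaining_high, 35)
  expect_equal(got$hcq, 35 / 1.5)
  # global scaling leaves HCQ unchanged
  expect_equal(hcq(7.3 * sar, masks)$hcq, got$hcq, tolerance = 1e-12)
  # uniform SAR -> HCQ = 1
  expect_equal(hcq(array(2, dm), masks)$hcq, 1)
  expect_error(hcq(array(0, dm), masks), "unbounded")
})

test_that("steering optimizer honors its competitive contract", {
  toy <- fx_mirror_toy()
  plan <- optimize_steering(toy$fields, toy$model, toy$masks, toy$f,
                            seed = 1, n_random = 50)
  # beats uniform steering
  rho <- lookup_properties(toy$model, toy$f)$rho
  eval_full <- function(chi) {
    sar <- assemble_sar(toy$fields, chi, toy$model, toy$f)
    sa <- mass_average_5g(sar, rho, toy$masks$patient, toy$model$spacing)
    hcq(sa, toy$masks, rho)$hcq
  }
  expect_lte(plan$hcq, eval_full(matrix(c(1, 1) / sqrt(2), 1)) + 1e-12)
  # beats its own random competitors (monotone acceptance)
  set.seed(1)
  for (r in 1:25) {
    chi_r <- matrix(complex(real = rnorm(2), imaginary = rnorm(2)), 1)
    expect_lte(plan$hcq, eval_full(chi_r) + 1e-12)
  }
  # mirror symmetry: optimal amplitudes agree
  amps <- Mod(plan$chi)
  expect_lt(abs(amps[1] - amps[2]) / max(amps), 0.05)
  # power table sums to 100%
  expect_equal(sum(plan$power_table), 100, tolerance = 1e-9)
  # single channel: HCQ invariant to phase and amplitude of chi
  one <- list(list(toy$fields[[1]][[1]]))
  p1 <- optimize_steering(one, toy$model, toy$masks, toy$f, seed = 2,
                          n_random = 3)
  sar_a <- assemble_sar(one, matrix(1 + 0i), toy$model, toy$f)
  sar_b <- assemble_sar(one, matrix(0.3 - 2i), toy$model, toy$f)
  sa_a <- mass_average_5g(sar_a, rho, toy$masks$patient, toy$model$spacing)
  sa_b <- mass_average_5g(sar_b, rho, toy$masks$patient, toy$model$spacing)
  expect_equal(hcq(sa_a, toy$masks, rho)$hcq, hcq(sa_b, toy$masks, rho)$hcq,
               tolerance = 1e-9)
  expect_equal(p1$hcq, hcq(sa_a, toy$masks, rho)$hcq, tolerance = 1e-9)
})

test_that("plan serialization carries steering and power accounting", {
  toy <- fx_mirror_toy()
  plan <- optimize_steering(toy$fields, toy$model, toy$masks, toy$f,
                            seed = 1, n_random = 10)
  tf <- tempfile(fileext = ".json")
  write_plan(plan, tf)
  j <- jsonlite::read_json(tf, simplifyVector = TRUE)
  expect_equal(j$hcq, plan$hcq)
  expect_equal(sum(j$power_table), 100, tolerance = 1e-6)
  expect_equal(power_frequency_totals(plan$power_table),
               colSums(plan$power_table))
})
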