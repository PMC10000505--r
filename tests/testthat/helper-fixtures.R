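# Shared fixtures, memoized so expensive objects are built once per run.
# Problem sizes are deliberately desk-scale: 8-10 mm lattices and small
# surface grids exercise every code path of the design chain.

.fx <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fx[[key]])) .fx[[key]] <- builder()
  .fx[[key]]
}

# Layered sphere phantom (study shells/outer radius, thinner bolus, 8 mm).
fx_sphere <- function() memo("sphere", function() {
  suppressWarnings(build_layered_sphere_phantom(
    phantom_spec(bolus_thickness = 30), spacing = 8))
})

# Same phantom with a centered deep tumor (symmetric toy problems).
fx_sphere_tumor <- function() memo("sphere_tumor", function() {
  suppressWarnings(build_layered_sphere_phantom(
    phantom_spec(bolus_thickness = 30,
                 tumor = list(center = c(0, 0, 0), radius = 20)),
    spacing = 8))
})

# Mid-bolus sphere the antennas sit on for the sphere phantoms.
fx_pose_sphere <- function() ellipsoid(rep(96.9 + 15, 3))

fx_masks_tumor <- function() memo("masks_tumor", function() {
  build_evaluation_masks(fx_sphere_tumor(), p = 50)
})

# 24-node interpolation bank at 500 MHz on the plain sphere phantom.
fx_bank <- function() memo("bank", function() {
  g <- spread_surface_grid(fx_pose_sphere(), 24, seed = 2, n_starts = 2,
                           maxit = 150)
  build_interpolation_bank(fx_sphere(), g, frequencies = 500e6)
})

# Bank on the tumor phantom at the deep-penetration frequency (array-design
# tests exercise a centered deep target).
fx_bank_tumor <- function() memo("bank_tumor", function() {
  g <- spread_surface_grid(fx_pose_sphere(), 24, seed = 2, n_starts = 2,
                           maxit = 150)
  build_interpolation_bank(fx_sphere_tumor(), g, frequencies = 250e6)
})

# Homogeneous muscle block with a centered synthetic pose (power checks).
fx_pose_centered <- function() {
  structure(list(theta = 0, phi = 0, surface_point = c(0, 0, 0),
                 O = c(0, 0, -14), O_phase = c(0, 0, 0),
                 U = c(1, 0, 0), V = c(0, 1, 0), W = c(0, 0, 1),
                 retraction = 0, phase_center_offset = 14),
            class = "antenna_pose")
}

fx_muscle_block <- function(spacing = 6, half_mm = 150) {
  n <- 2L * ceiling(half_mm / spacing) + 1L
  tissue_model(array(TISSUE_LABELS[["muscle"]], c(n, n, n)), spacing)
}

# 1-D slab fixture: a bar of CSF (zero perfusion) between two water faces
# held at the coolant temperature through a very large film coefficient.
slab_model <- function(n_cells, spacing) {
  lab <- array(0L, c(n_cells + 2L, 3L, 3L))
  lab[2:(n_cells + 1L), 2L, 2L] <- TISSUE_LABELS[["csf"]]
  lab[c(1L, n_cells + 2L), 2L, 2L] <- TISSUE_LABELS[["water"]]
  tissue_model(lab, spacing)
}

# Constant vector field helper with lattice attributes.
const_field <- function(dm, vec, spacing = 8, origin = NULL) {
  origin <- origin %||% (-(dm - 1) / 2 * spacing)
  E <- array(0i, c(dm, 3L))
  for (k in 1:3) E[, , , k] <- vec[k]
  attr(E, "spacing") <- rep(spacing, 3)
  attr(E, "origin") <- origin
  E
}

make_pose <- function(O, U, V, W) {
  structure(list(theta = NA, phi = NA, surface_point = O, O = O,
                 O_phase = O + 14 * W, U = U, V = V, W = W, retraction = 0,
                 phase_center_offset = 14),
            class = "antenna_pose")
}

# 30 seeded noisy oracle pair experiments at 500 MHz (coupling recovery);
# returns per-pair relative error of k and the fitted coupling model.
fx_coupling_recovery <- function() memo("coupling_recovery", function() {
  mod <- fx_sphere()
  e <- fx_pose_sphere()
  c_true <- 0.05 + 0.02i
  props <- lookup_properties(mod, 500e6)
  set.seed(42)
  co_a <- helmetplan:::sample_surface_uniform(e, 1)
  active <- antenna_frame(e, co_a[1, 1], co_a[1, 2], retract = FALSE)
  co_p <- helmetplan:::sample_surface_uniform(e, 30)
  seeds <- helmetplan:::child_seeds(42, 30)
  es <- complex(30); ks <- complex(30); ktrue <- complex(30)
  for (i in 1:30) {
    passive <- antenna_frame(e, co_p[i, 1], co_p[i, 2], retract = FALSE)
    pe <- oracle_pair_experiment(mod, active, passive, 500e6, c_true,
                                 noise = 0.01, seed = seeds[i], props = props)
    es[i] <- pe$e_AP
    ks[i] <- estimate_k_by_decorrelation(pe$EA, pe$EP, pe$EAP)
    ktrue[i] <- pe$k_true
  }
  fit <- fit_coupling_coefficient(es, ks, f = 500e6)
  list(c_true = c_true, fit = fit,
       k_rel_err = Mod(ks - ktrue) / Mod(ktrue))
})

# Mean interpolation distribution error over fixed query poses for grid
# densities 55 / 110 / 221 (coarse 10 mm lattice).
fx_interp_convergence <- function() memo("interp_convergence", function() {
  mod <- suppressWarnings(build_layered_sphere_phantom(
    phantom_spec(bolus_thickness = 30), spacing = 10))
  e <- fx_pose_sphere()
  pm <- helmetplan:::patient_mask(mod)
  set.seed(99)
  qs <- helmetplan:::sample_surface_uniform(e, 10)
  vapply(c(55L, 110L, 221L), function(np) {
    g <- spread_surface_grid(e, np, seed = 5, n_starts = 2, maxit = 250)
    bank <- build_interpolation_bank(mod, g, frequencies = 500e6,
                                     n_ray_samples = 8)
    errs <- vapply(seq_len(nrow(qs)), function(i) {
      th <- qs[i, 1]; ph <- qs[i, 2]
      Ei <- interpolate_antenna_field(bank, th, ph, 500e6)
      pose <- antenna_frame(e, th, ph)
      Es <- oracle_antenna_field(mod, pose, 500e6, n_ray_samples = 8)
      field_error_metrics(Es, Ei, pm, pose$U, mod,
                          mass_average = FALSE)$dis
    }, numeric(1))
    mean(errs)
  }, numeric(1))
})

# Symmetric two-channel toy at 250 MHz: mirror-opposed antennas around the
# centered tumor; fields plus masked-voxel caches for fast HCQ evaluation.
fx_mirror_toy <- function() memo("mirror_toy", function() {
  mod <- fx_sphere_tumor()
  masks <- fx_masks_tumor()
  e <- fx_pose_sphere()
  f <- 250e6
  p1 <- antenna_frame(e, pi / 2, 0, retract = FALSE)
  p2 <- antenna_frame(e, pi / 2, pi, retract = FALSE)
  fields <- list(list(oracle_antenna_field(mod, p1, f),
                      oracle_antenna_field(mod, p2, f)))
  props <- lookup_properties(mod, f)
  n <- prod(dim(mod$labels))
  sel_t <- which(as.vector(masks$target))
  sel_r <- which(as.vector(masks$remaining))
  grab <- function(E, sel) cbind(E[sel], E[sel + n], E[sel + 2L * n])
  list(model = mod, masks = masks, f = f, fields = fields,
       poses = list(p1, p2),
       coef_t = (0.5 * props$sigma / props$rho)[sel_t],
       coef_r = (0.5 * props$sigma / props$rho)[sel_r],
       E_t = lapply(fields[[1]], grab, sel = sel_t),
       E_r = lapply(fields[[1]], grab, sel = sel_r))
})

# Unaveraged HCQ of the mirror toy for a 2-channel steering (subset SAR).
toy_hcq <- function(toy, chi) {
  sar_of <- function(Elist, coef) {
    tot <- chi[1] * Elist[[1]] + chi[2] * Elist[[2]]
    coef * rowSums(Mod(tot)^2)
  }
  st <- sar_of(toy$E_t, toy$coef_t)
  sr <- sar_of(toy$E_r, toy$coef_r)
  low <- helmetplan:::tail_mean(st, rep(1, length(st)), toy$masks$p, "low")
  high <- helmetplan:::tail_mean(sr, rep(1, length(sr)), toy$masks$q, "high")
  high / low
}
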