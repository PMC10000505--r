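# Voxel tissue models: layered phantoms, synthetic patients, property lookups.

#' Voxel tissue model
#'
#' Container for a cell-centered integer label grid with per-tissue,
#' per-frequency dielectric and thermal properties. Axes follow radiological
#' convention: x right, y anterior, z cranial; indices are 0-based in the
#' coordinate mapping (voxel (0,0,0) center sits at `origin`).
#'
#' @param labels 3-D integer array of tissue label codes (see `TISSUE_LABELS`).
#' @param spacing voxel size per axis in mm (scalar recycled).
#' @param origin mm coordinates of the center of voxel (0,0,0).
#' @param properties property list from [load_property_table()].
#' @param label_map named integer vector mapping tissue names to label codes.
#' @return An object of class `tissue_model`.
#' @export
tissue_model <- function(labels, spacing, origin = NULL,
                         properties = load_property_table(),
                         label_map = TISSUE_LABELS) {
  spacing <- rep(as.numeric(spacing), length.out = 3L)
  stopifnot(length(dim(labels)) == 3L, all(spacing > 0))
  storage.mode(labels) <- "integer"
  if (is.null(origin)) origin <- -(dim(labels) - 1) / 2 * spacing
  present <- setdiff(sort(unique(as.vector(labels))), 0L)
  known <- label_map[label_map != 0L]
  if (!all(present %in% known)) {
    stop("labels without a property row: ",
         paste(setdiff(present, known), collapse = ", "))
  }
  structure(list(labels = labels, spacing = spacing, origin = as.numeric(origin),
                 properties = properties, label_map = label_map,
                 frequencies = properties$frequencies),
            class = "tissue_model")
}

#' @export
print.tissue_model <- function(x, ...) {
  dm <- dim(x$labels)
  cat("Voxel tissue model:", paste(dm, collapse = " x "), "voxels @",
      paste(signif(x$spacing, 3), collapse = "/"), "mm\n")
  present <- sort(unique(as.vector(x$labels)))
  nm <- names(x$label_map)[match(present, x$label_map)]
  cnt <- tabulate(as.vector(x$labels) + 1L, nbins = max(present) + 1L)[present + 1L]
  for (i in seq_along(present)) {
    cat(sprintf("  %2d %-14s %8d voxels (%.1f mL)\n", present[i],
                nm[i] %||% "?", cnt[i], cnt[i] * prod(x$spacing) / 1000))
  }
  invisible(x)
}

# Voxel volume in m^3.
voxel_volume_m3 <- function(model) prod(model$spacing) * 1e-9

#' Layered-sphere phantom specification
#'
#' @param outer_radius outer phantom radius, mm.
#' @param shell_thicknesses thicknesses in mm of the skin, bone and CSF shells
#'   (outermost first); the remaining core is brain.
#' @param bolus_thickness water bolus annulus thickness, mm.
#' @param tumor optional list with `center` (mm) and `radius` (mm).
#' @export
phantom_spec <- function(outer_radius = 96.9,
                         shell_thicknesses = c(skin = 6.3, bone = 6.8, csf = 10.7),
                         bolus_thickness = 50, tumor = NULL) {
  if (outer_radius <= 0 || any(shell_thicknesses < 0) || bolus_thickness < 0) {
    stop("phantom radii and thicknesses must be nonnegative")
  }
  if (sum(shell_thicknesses) >= outer_radius) {
    stop("shells must leave room for the brain core")
  }
  shell_thicknesses <- stats::setNames(rep(shell_thicknesses, length.out = 3L),
                                       c("skin", "bone", "csf"))
  structure(list(outer_radius = outer_radius,
                 shell_thicknesses = shell_thicknesses,
                 bolus_thickness = bolus_thickness, tumor = tumor),
            class = "phantom_spec")
}

#' Build a layered spherical head phantom in a spherical water bolus
#'
#' Concentric shells (skin, bone, CSF) around a brain core, surrounded by a
#' water annulus and exterior air. Every voxel is labeled by the radius of its
#' center (winner-takes-all; no partial-volume weighting). Shells thinner than
#' one voxel are flagged in the `under_resolved` attribute of the returned
#' model rather than rejected.
#'
#' @param spec a [phantom_spec()].
#' @param spacing isotropic voxel size, mm (default 4).
#' @param margin air margin beyond the bolus, mm.
#' @return A [tissue_model()] centered at the origin.
#' @export
build_layered_sphere_phantom <- function(spec, spacing = 4, margin = 8) {
  stopifnot(inherits(spec, "phantom_spec"))
  rmax <- spec$outer_radius + spec$bolus_thickness + margin
  n <- 2L * ceiling(rmax / spacing) + 1L
  dm <- c(n, n, n)
  origin <- -(dm - 1) / 2 * spacing
  ctr <- voxel_centers(dm, rep(spacing, 3), origin)
  r <- sqrt(rowSums(ctr^2))
  th <- spec$shell_thicknesses
  r_core <- spec$outer_radius - sum(th)
  r_csf <- r_core + th[3L]
  r_bone <- r_csf + th[2L]
  lab <- integer(length(r))  # air
  lab[r <= spec$outer_radius + spec$bolus_thickness] <- TISSUE_LABELS[["water"]]
  lab[r <= spec$outer_radius] <- TISSUE_LABELS[["skin"]]
  lab[r <= r_bone] <- TISSUE_LABELS[["bone_cortical"]]
  lab[r <= r_csf] <- TISSUE_LABELS[["csf"]]
  lab[r <= r_core] <- TISSUE_LABELS[["brain_gray"]]
  if (!is.null(spec$tumor)) {
    d <- sqrt(rowSums(sweep(ctr, 2L, spec$tumor$center, "-")^2))
    lab[d <= spec$tumor$radius] <- TISSUE_LABELS[["tumor"]]
  }
  model <- tissue_model(array(lab, dm), spacing, origin)
  under <- names(th)[th > 0 & th < spacing]
  if (length(under)) {
    warning("shells thinner than one voxel: ", paste(under, collapse = ", "))
    attr(model, "under_resolved") <- under
  }
  model
}

#' Build a synthetic layered-head patient model with an embedded tumor
#'
#' Ellipsoidal head with skin/bone/CSF shells around gray- and white-matter
#' compartments, muscle fill caudal to the brain stem (emulating the rest of
#' the body), two eye globes, and an optional spherical tumor blob placed in
#' the dorsal brain. The default tumor volume is 126 mL, the medulloblastoma
#' volume the study conditions assume. Deterministic under a fixed seed (the
#' seed jitters the tumor center by at most 2 mm).
#'
#' @param seed integer seed controlling the tumor-center jitter.
#' @param head_radii semi-axes of the scalp ellipsoid (x, y, z), mm.
#' @param tumor_spec list with `volume_ml` (default 126) and optionally
#'   `center` (mm, relative to head center); `NULL` for no tumor.
#' @param spacing isotropic voxel size, mm.
#' @param bolus_thickness water layer thickness, mm.
#' @return A [tissue_model()].
#' @export
build_synthetic_patient <- function(seed = 1L,
                                    head_radii = c(75, 92, 94),
                                    tumor_spec = list(volume_ml = 126),
                                    spacing = 4, bolus_thickness = 50) {
  rmax <- max(head_radii) + bolus_thickness + 2 * spacing
  n <- 2L * ceiling(rmax / spacing) + 1L
  dm <- c(n, n, n)
  origin <- -(dm - 1) / 2 * spacing
  ctr <- voxel_centers(dm, rep(spacing, 3), origin)
  # normalized ellipsoidal radius and an approximate inward depth (mm)
  u <- sweep(ctr, 2L, head_radii, "/")
  rho_e <- sqrt(rowSums(u^2))
  grad <- sqrt(rowSums(sweep(u, 2L, head_radii, "/")^2))
  depth <- ifelse(grad > 0, (1 - rho_e) / grad, Inf)   # >0 inside the scalp
  lab <- integer(nrow(ctr))
  bolus <- rho_e <= 1 + bolus_thickness / min(head_radii) * 0.999 & depth <= 0
  # water bolus: within offset surface (approximated by depth in [-bolus, 0])
  lab[depth <= 0 & depth >= -bolus_thickness] <- TISSUE_LABELS[["water"]]
  inside <- depth > 0
  lab[inside] <- TISSUE_LABELS[["skin"]]
  lab[inside & depth > 6.3] <- TISSUE_LABELS[["bone_cortical"]]
  lab[inside & depth > 6.3 + 6.8] <- TISSUE_LABELS[["csf"]]
  lab[inside & depth > 6.3 + 6.8 + 10.7] <- TISSUE_LABELS[["brain_gray"]]
  lab[inside & depth > 6.3 + 6.8 + 10.7 + 15] <- TISSUE_LABELS[["brain_white"]]
  # caudal fill below the brain stem: muscle
  caudal <- inside & ctr[, 3L] < -0.55 * head_radii[3L]
  lab[caudal] <- TISSUE_LABELS[["muscle"]]
  # eye globes, anterior, near the surface
  for (sx in c(-1, 1)) {
    eye_c <- c(sx * 0.40 * head_radii[1L], 0.80 * head_radii[2L], 0.02 * head_radii[3L])
    d <- sqrt(rowSums(sweep(ctr, 2L, eye_c, "-")^2))
    lab[d <= 11 & inside] <- TISSUE_LABELS[["eye"]]
  }
  if (!is.null(tumor_spec)) {
    vol_ml <- tumor_spec$volume_ml %||% 126
    r_t <- (3 * vol_ml * 1000 / (4 * pi))^(1 / 3)   # mm
    set.seed(as.integer(seed))
    jit <- stats::runif(3, -2, 2)
    t_c <- (tumor_spec$center %||% c(0, -28, -20)) + jit
    brainish <- lab %in% TISSUE_LABELS[c("brain_gray", "brain_white")]
    d <- sqrt(rowSums(sweep(ctr, 2L, t_c, "-")^2))
    sel <- d <= r_t & brainish
    got_ml <- sum(sel) * spacing^3 / 1000
    if (got_ml < 0.95 * vol_ml) {
      stop("tumor volume unachievable inside the brain compartment: ",
           sprintf("%.1f of %.1f mL", got_ml, vol_ml))
    }
    lab[sel] <- TISSUE_LABELS[["tumor"]]
  }
  tissue_model(array(lab, dm), spacing, origin)
}

#' Per-voxel property maps at an operating frequency
#'
#' Expands the tissue property table over the label grid, returning per-voxel
#' maps of permittivity, conductivity, density and intrinsic impedance. Air /
#' exterior voxels receive the free-space impedance (376.7 Ohm).
#'
#' @param model a [tissue_model()].
#' @param f frequency in Hz; must belong to the model's frequency set.
#' @param impedance `"complex"` (lossy intrinsic impedance, default) or
#'   `"lossless"`.
#' @return list of 3-D arrays: `eps_r`, `sigma`, `rho`, `eta` (complex),
#'   plus thermal maps `cp`, `k_th`, `perfusion`.
#' @export
lookup_properties <- function(model, f, impedance = c("complex", "lossless")) {
  impedance <- match.arg(impedance)
  if (!f %in% model$frequencies) {
    stop("frequency ", f, " Hz is not in the model's frequency set")
  }
  tab <- model$properties$table
  tab_f <- tab[tab$frequency == f, ]
  maxlab <- max(model$label_map)
  eps_l <- rep(1, maxlab + 1L); sig_l <- rep(0, maxlab + 1L)
  rho_l <- rep(1.2, maxlab + 1L); cp_l <- rep(1004, maxlab + 1L)
  kth_l <- rep(0.026, maxlab + 1L); w_l <- rep(0, maxlab + 1L)
  for (i in seq_len(nrow(tab_f))) {
    code <- model$label_map[[tab_f$tissue[i]]]
    if (is.na(code)) next
    eps_l[code + 1L] <- tab_f$eps_r[i]; sig_l[code + 1L] <- tab_f$sigma[i]
    rho_l[code + 1L] <- tab_f$rho[i]; cp_l[code + 1L] <- tab_f$cp[i]
    kth_l[code + 1L] <- tab_f$k_th[i]; w_l[code + 1L] <- tab_f$perfusion[i]
  }
  idx <- as.vector(model$labels) + 1L
  dm <- dim(model$labels)
  eta_l <- intrinsic_impedance(eps_l, sig_l, f, mode = impedance)
  list(eps_r = array(eps_l[idx], dm), sigma = array(sig_l[idx], dm),
       rho = array(rho_l[idx], dm), eta = array(eta_l[idx], dm),
       cp = array(cp_l[idx], dm), k_th = array(kth_l[idx], dm),
       perfusion = array(w_l[idx], dm))
}

# Labels regarded as part of the patient body (thermal / SAR domain).
patient_mask <- function(model) {
  excl <- TISSUE_LABELS[c("exterior", "water", "pharynx_air")]
  array(!(model$labels %in% excl), dim(model$labels))
}

#' Write / read a tissue model label grid as NIfTI
#'
#' Labels are stored as int16 with spacing in the header; the property table
#' travels separately (see [load_property_table()]).
#' @param model a [tissue_model()].
#' @param path output `.nii`/`.nii.gz` path.
#' @export
write_tissue_model <- function(model, path) {
  arr <- model$labels
  attr(arr, "pixdim") <- model$spacing
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "int16"), path)
  invisible(path)
}

#' @rdname write_tissue_model
#' @param origin mm coordinate of the first voxel center (NIfTI stores spacing
#'   only in this writer; supply the origin used at write time).
#' @export
read_tissue_model <- function(path, origin = NULL,
                              properties = load_property_table()) {
  img <- RNifti::readNifti(path)
  spacing <- RNifti::pixdim(img)[1:3]
  labels <- array(as.integer(img), dim(img)[1:3])
  tissue_model(labels, spacing, origin, properties)
}
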