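# Field interpolation: H-surrogate transform, rigid field transformation,
# barycentric blending over the surface grid, and field-error metrics.

#' Impedance surrogate of an E-field
#'
#' Divides (or multiplies back) the complex vector E-field voxelwise by the
#' local intrinsic impedance, yielding a surrogate of the antenna's H-field.
#' Biological tissues are essentially non-magnetic, so this surrogate is far
#' less sensitive to the anatomy under rigid transformation; the division is
#' exactly undone on restoration.
#'
#' @param E complex 4-D field array (nx, ny, nz, 3).
#' @param eta complex 3-D impedance array (from [lookup_properties()]).
#' @return field array of the same shape.
#' @export
to_h_surrogate <- function(E, eta) {
  if (any(abs(eta) < .Machine$double.eps)) stop("zero impedance voxel")
  out <- E / as.vector(eta)
  attributes(out) <- attributes(E)
  out
}

#' @rdname to_h_surrogate
#' @export
from_h_surrogate <- function(H, eta) {
  out <- H * as.vector(eta)
  attributes(out) <- attributes(H)
  out
}

#' Rigidly transform a vector field between two antenna frames
#'
#' Applies the rigid map composed of a translation of the source origin to
#' zero, the rotation taking frame `from` onto frame `to`, and a translation
#' to the target origin -- to both sample positions and vector components.
#' The result is resampled onto the same fixed lattice (trilinear on real and
#' imaginary parts); samples falling outside the lattice are set to zero and
#' their fraction recorded in the `outside` attribute. Identity maps and pure
#' whole-voxel translations take exact paths (no resampling loss).
#'
#' @param H complex 4-D field array with `spacing`/`origin` attributes.
#' @param from,to [antenna_frame()] poses.
#' @return transformed field array.
#' @export
transform_field <- function(H, from, to) {
  sp <- attr(H, "spacing"); og <- attr(H, "origin")
  dm <- dim(H)[1:3]
  R <- frame_rotation(from, to)
  tvec <- to$O - drop(R %*% from$O)
  if (max(abs(R - diag(3))) < 1e-12) {
    shift <- tvec / sp
    if (max(abs(shift - round(shift))) < 1e-9) {
      sh <- as.integer(round(shift))
      if (all(sh == 0L)) {
        out <- H
        attr(out, "outside") <- 0
        return(out)
      }
      out <- array(0i, dim(H))
      src1 <- pmax(1L, 1L - sh[1L]):pmin(dm[1L], dm[1L] - sh[1L])
      src2 <- pmax(1L, 1L - sh[2L]):pmin(dm[2L], dm[2L] - sh[2L])
      src3 <- pmax(1L, 1L - sh[3L]):pmin(dm[3L], dm[3L] - sh[3L])
      out[src1 + sh[1L], src2 + sh[2L], src3 + sh[3L], ] <-
        H[src1, src2, src3, , drop = FALSE]
      attributes(out) <- attributes(H)
      attr(out, "outside") <- 1 - length(src1) * length(src2) * length(src3) / prod(dm)
      return(out)
    }
  }
  X <- voxel_centers(dm, sp, og)
  # inverse map: source position of each output voxel
  Xs <- sweep(X, 2L, to$O, "-") %*% R  # (x - O_to) %*% R == t(R) applied rowwise
  Xs <- sweep(Xs, 2L, from$O, "+")
  samp <- trilinear_sample(H, Xs, sp, og, fill = 0)
  outv <- samp %*% t(R)
  out <- array(c(outv[, 1L], outv[, 2L], outv[, 3L]), dim(H))
  attributes(out) <- attributes(H)
  attr(out, "outside") <- attr(samp, "outside")
  out
}

#' Precompute an interpolation bank over a surface grid
#'
#' Runs the field oracle once per (grid node, frequency) and caches the
#' per-frequency impedance maps, mirroring the one-off batch of single
#' antenna simulations the interpolation scheme relies on.
#'
#' @param model a [tissue_model()].
#' @param grid a [spread_surface_grid()] result.
#' @param frequencies subset of the model's frequency set, Hz.
#' @param impedance impedance mode passed to [lookup_properties()].
#' @param ... passed to [oracle_antenna_field()].
#' @return object of class `interpolation_bank`.
#' @export
build_interpolation_bank <- function(model, grid,
                                     frequencies = model$frequencies,
                                     impedance = "complex", ...) {
  poses <- lapply(seq_along(grid$theta), function(i) {
    antenna_frame(grid$ellipsoid, grid$theta[i], grid$phi[i])
  })
  props <- lapply(frequencies, function(f) lookup_properties(model, f, impedance))
  names(props) <- as.character(frequencies)
  fields <- lapply(seq_along(frequencies), function(fi) {
    lapply(poses, function(p) {
      oracle_antenna_field(model, p, frequencies[fi], props = props[[fi]], ...)
    })
  })
  names(fields) <- as.character(frequencies)
  structure(list(grid = grid, poses = poses, fields = fields,
                 eta = lapply(props, `[[`, "eta"),
                 frequencies = frequencies, model_dim = dim(model$labels),
                 spacing = model$spacing, origin = model$origin),
            class = "interpolation_bank")
}

#' @export
print.interpolation_bank <- function(x, ...) {
  cat(sprintf("Interpolation bank: %d nodes x %d frequencies on a %s lattice\n",
              length(x$poses), length(x$frequencies),
              paste(x$model_dim, collapse = "x")))
  invisible(x)
}

#' Approximate the E-field of an antenna at an arbitrary pose
#'
#' Executes the surface interpolation scheme: locate the triangular patch of
#' the query pose, divide each corner field by the local impedance (H
#' surrogate), rigidly transform each surrogate from its corner frame to the
#' query frame, restore the E-field by multiplying the impedance back, and
#' blend the three transformed fields with the patch area-ratio weights.
#'
#' @param bank an [build_interpolation_bank()] result.
#' @param theta,phi query surface coordinates, radians.
#' @param f frequency, Hz (must be in the bank).
#' @return complex 4-D field array; attributes `patch` (node indices),
#'   `weights`, `clamped`, `outside` (worst resampled fraction).
#' @export
interpolate_antenna_field <- function(bank, theta, phi, f) {
  key <- as.character(f)
  if (is.null(bank$fields[[key]])) stop("frequency not in bank")
  patch <- locate_patch(bank$grid, theta, phi)
  qpose <- antenna_frame(bank$grid$ellipsoid, theta, phi)
  eta <- bank$eta[[key]]
  acc <- NULL
  outside <- 0
  for (m in seq_len(3L)) {
    w <- patch$weights[m]
    if (w == 0) next
    node <- patch$nodes[m]
    H <- to_h_surrogate(bank$fields[[key]][[node]], eta)
    Ht <- transform_field(H, bank$poses[[node]], qpose)
    outside <- max(outside, attr(Ht, "outside") %||% 0)
    Et <- from_h_surrogate(Ht, eta)
    acc <- if (is.null(acc)) w * Et else acc + w * Et
  }
  attr(acc, "spacing") <- bank$spacing
  attr(acc, "origin") <- bank$origin
  attr(acc, "frequency") <- f
  attr(acc, "patch") <- patch$nodes
  attr(acc, "weights") <- patch$weights
  attr(acc, "clamped") <- patch$clamped
  attr(acc, "outside") <- outside
  acc
}

#' Field approximation error metrics
#'
#' Four average relative error measures between a reference and an
#' approximated complex vector E-field over an evaluation mask: distribution
#' (relative vector difference), amplitude (of the co-polarized component),
#' phase (wrapped difference of the co-polarized component, normalized by
#' pi), and direction (angle between the per-voxel amplitude vectors,
#' normalized by pi/2). Both fields are mass-averaged component-wise with the
#' 5 g scheme before comparison.
#'
#' @param E_ref,E_approx complex 4-D field arrays on the model lattice.
#' @param mask logical 3-D evaluation mask.
#' @param U antenna polarization unit vector.
#' @param model [tissue_model()] providing density for the mass averaging.
#' @param mass_average apply the 5 g pre-averaging (default TRUE).
#' @return object of class `field_error_report`: `dis`, `abs`, `ang`, `dir`
#'   (fractions), `n_excluded` (zero-reference voxels dropped from ratios).
#' @export
field_error_metrics <- function(E_ref, E_approx, mask, U, model,
                                mass_average = TRUE) {
  stopifnot(identical(dim(E_ref), dim(E_approx)), any(mask))
  if (mass_average) {
    rho <- lookup_properties(model, model$frequencies[1L])$rho
    pm <- patient_mask(model)
    E_ref <- mass_average_field(E_ref, rho, pm, model$spacing)
    E_approx <- mass_average_field(E_approx, rho, pm, model$spacing)
  }
  n <- prod(dim(E_ref)[1:3])
  idx <- which(as.vector(mask))
  comp <- function(E, k) E[idx + (k - 1L) * n]
  Es <- cbind(comp(E_ref, 1L), comp(E_ref, 2L), comp(E_ref, 3L))
  Ei <- cbind(comp(E_approx, 1L), comp(E_approx, 2L), comp(E_approx, 3L))
  ns <- sqrt(rowSums(abs(Es)^2))
  ok <- ns > .Machine$double.eps
  dis <- mean(sqrt(rowSums(abs(Es - Ei)[ok, , drop = FALSE]^2)) / ns[ok])
  us <- drop(Es %*% U); ui <- drop(Ei %*% U)
  oku <- abs(us) > .Machine$double.eps
  abse <- mean(abs(abs(us[oku]) - abs(ui[oku])) / abs(us[oku]))
  ang <- mean(abs(wrap_angle(Arg(us[oku]) - Arg(ui[oku])))) / pi
  As <- abs(Es); Ai <- abs(Ei)
  nA <- sqrt(rowSums(As^2)); nB <- sqrt(rowSums(Ai^2))
  okd <- nA > .Machine$double.eps & nB > .Machine$double.eps
  cosang <- clamp(rowSums((As * Ai)[okd, , drop = FALSE]) / (nA[okd] * nB[okd]), -1, 1)
  dire <- mean(acos(cosang)) / (pi / 2)
  structure(list(dis = dis, abs = abse, ang = ang, dir = dire,
                 n_excluded = sum(!ok)),
            class = "field_error_report")
}

#' @export
print.field_error_report <- function(x, ...) {
  cat(sprintf("Field errors: DIS %.1f%%  ABS %.1f%%  ANG %.1f%%  DIR %.1f%%\n",
              100 * x$dis, 100 * x$abs, 100 * x$ang, 100 * x$dir))
  invisible(x)
}
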