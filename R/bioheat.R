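# Steady-state Pennes bioheat solver on the voxel lattice with convective
# (Robin) boundaries, power scaling to the healthy-tissue limit, and target
# temperature indexes.

# Blood properties for the perfusion sink (Pennes constants).
BLOOD_RHO_CP <- 3.6e6   # J/m^3/K
BLOOD_TEMPERATURE <- 37 # degC

#' Power loss density of a steering plan
#'
#' PLD = kappa sum_f 0.5 sigma_f |E_f|^2 (W/m^3) with E_f the steered total
#' field per frequency. Unlike the planning SAR, the PLD is neither mass
#' averaged nor masked; it equals kappa * rho * SAR pointwise.
#'
#' @param fields nested list `fields[[f]][[c]]` of complex field arrays.
#' @param chi complex steering matrix, n_freq x n_channel.
#' @param model a [tissue_model()].
#' @param frequencies frequency values, Hz.
#' @param kappa power scaling factor.
#' @return 3-D PLD array, W/m^3.
#' @export
pld_from_plan <- function(fields, chi, model, frequencies, kappa = 1) {
  sar <- assemble_sar(fields, chi, model, frequencies)
  rho <- lookup_properties(model, frequencies[1L])$rho
  kappa * rho * sar
}

#' Solve the steady-state Pennes bioheat equation
#'
#' Finite-volume 7-point discretization of
#' div(k grad T) - rho_b c_b w (T - T_b) + PLD = 0 over the patient voxels,
#' with Robin (convective) conditions h (T - T_inf) on exterior faces: faces
#' facing water use `h_water`/`water_temp`, all other exterior faces (air,
#' internal airways) use `h_air`/`air_temp`. Face conductances combine the
#' half-cell conduction path with the convection coefficient in series;
#' interior faces use the harmonic mean of the two cell conductivities. The
#' water bolus itself is not meshed; it acts only through its boundary
#' condition.
#'
#' @param model a [tissue_model()].
#' @param pld 3-D heat source array, W/m^3.
#' @param air_temp,water_temp coolant temperatures, degC.
#' @param h_air,h_water convection coefficients, W/m^2/K.
#' @return 3-D temperature array, degC (NA outside the patient).
#' @export
solve_pennes_steady <- function(model, pld, air_temp = 20, water_temp = 30,
                                h_air = 8, h_water = 100) {
  dm <- dim(model$labels)
  pm <- patient_mask(model)
  idx <- which(pm)
  nunk <- length(idx)
  if (nunk == 0L) stop("no patient voxels")
  props <- lookup_properties(model, model$frequencies[1L])
  kth <- as.vector(props$k_th); rho <- as.vector(props$rho)
  wml <- as.vector(props$perfusion)
  omega <- wml * rho * 1e-6 / 60  # ml/min/kg -> 1/s volumetric perfusion
  sp_m <- model$spacing * 1e-3
  vol <- prod(sp_m)
  gidx <- array(0L, dm); gidx[idx] <- seq_len(nunk)
  water_lab <- TISSUE_LABELS[["water"]]
  labs <- as.vector(model$labels)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  diag_acc <- numeric(nunk)
  rhs <- as.vector(pld)[idx] * vol
  strides <- c(1L, dm[1L], dm[1L] * dm[2L])
  ai <- arrayInd(idx, dm)
  for (ax in 1:3) {
    face_area <- vol / sp_m[ax]
    half <- sp_m[ax] / 2
    for (dirn in c(-1L, 1L)) {
      pos <- ai[, ax] + dirn
      inb <- pos >= 1L & pos <= dm[ax]
      nb <- idx + dirn * strides[ax]
      nb[!inb] <- NA_integer_
      nb_in <- inb & pm[ifelse(is.na(nb), 1L, nb)]
      # interior faces
      w <- which(nb_in)
      if (length(w)) {
        ki <- kth[idx[w]]; kj <- kth[nb[w]]
        g <- face_area * 2 * ki * kj / (ki + kj) / sp_m[ax]
        ii <- c(ii, gidx[idx[w]]); jj <- c(jj, gidx[nb[w]]); xx <- c(xx, -g)
        diag_acc[gidx[idx[w]]] <- diag_acc[gidx[idx[w]]] + g
      }
      # boundary (Robin) faces
      wb <- which(!nb_in)
      if (length(wb)) {
        is_water <- !is.na(nb[wb]) & labs[ifelse(is.na(nb[wb]), 1L, nb[wb])] == water_lab
        hcoef <- ifelse(is_water, h_water, h_air)
        tinf <- ifelse(is_water, water_temp, air_temp)
        g <- face_area / (half / kth[idx[wb]] + 1 / hcoef)
        diag_acc[gidx[idx[wb]]] <- diag_acc[gidx[idx[wb]]] + g
        rhs[gidx[idx[wb]]] <- rhs[gidx[idx[wb]]] + g * tinf
      }
    }
  }
  # perfusion sink toward arterial blood
  perf <- BLOOD_RHO_CP * omega[idx] * vol
  diag_acc <- diag_acc + perf
  rhs <- rhs + perf * BLOOD_TEMPERATURE
  if (all(diag_acc <= 0)) stop("singular thermal system")
  A <- Matrix::sparseMatrix(i = c(seq_len(nunk), ii), j = c(seq_len(nunk), jj),
                            x = c(diag_acc, xx), dims = c(nunk, nunk))
  Tsol <- as.vector(Matrix::solve(A, rhs))
  out <- array(NA_real_, dm)
  out[idx] <- Tsol
  out
}

#' Target temperature indexes T50 and T90
#'
#' The minimum temperature achieved within the highest 50% (T50) and highest
#' 90% (T90) of the temperature distribution in the target, i.e. the 50th and
#' 10th volume-weighted percentiles (nearest rank).
#'
#' @param temperature 3-D temperature array, degC.
#' @param target logical target mask.
#' @return named vector c(T50 = , T90 = ).
#' @export
temperature_indexes <- function(temperature, target) {
  tv <- temperature[target]
  if (!length(tv)) stop("empty target")
  tv <- sort(tv, decreasing = TRUE)
  nr <- function(pct) tv[max(1L, ceiling(pct / 100 * length(tv)))]
  c(T50 = nr(50), T90 = nr(90))
}

#' Scale plan power to the healthy-tissue temperature limit
#'
#' Finds the power scaling factor kappa such that the maximum steady-state
#' temperature over the healthy (non-tumor) patient tissue equals `limit`
#' (42 degC by default, the central-nervous-system toxicity limit). The
#' steady-state solution is affine in kappa, and the healthy maximum is
#' strictly increasing in kappa, so the root is found by bisection after
#' bracketing. Two linear solves (zero power and unit power) suffice.
#'
#' @param model a [tissue_model()].
#' @param fields,chi,frequencies the steered plan (see [pld_from_plan()]).
#' @param limit healthy-tissue temperature limit, degC.
#' @param tol absolute tolerance on the achieved maximum, degC.
#' @param ... boundary-condition arguments for [solve_pennes_steady()].
#' @return object of class `thermal_result`: `temperature` (degC), `kappa`,
#'   `max_healthy`, `T50`, `T90`.
#' @export
scale_power_to_limit <- function(model, fields, chi, frequencies, limit = 42,
                                 tol = 0.01, ...) {
  pld1 <- pld_from_plan(fields, chi, model, frequencies, kappa = 1)
  T0 <- solve_pennes_steady(model, array(0, dim(model$labels)), ...)
  T1 <- solve_pennes_steady(model, pld1, ...)
  healthy <- patient_mask(model) & model$labels != TISSUE_LABELS[["tumor"]]
  base <- T0[healthy]; delta <- T1[healthy] - T0[healthy]
  maxh <- function(kappa) max(base + kappa * delta)
  if (maxh(0) > limit + tol) stop("limit below the zero-power temperature")
  if (max(delta) <= 0) stop("plan deposits no power in healthy tissue")
  hi <- 1
  while (maxh(hi) < limit) hi <- hi * 2
  lo <- 0
  while (maxh(hi) - maxh(lo) > 0 && (hi - lo) > 0) {
    mid <- (lo + hi) / 2
    if (abs(maxh(mid) - limit) <= tol * 0.5) { lo <- hi <- mid; break }
    if (maxh(mid) < limit) lo <- mid else hi <- mid
    if ((hi - lo) < 1e-12 * max(1, hi)) break
  }
  kappa <- (lo + hi) / 2
  temp <- T0 + kappa * (T1 - T0)
  target <- array(model$labels == TISSUE_LABELS[["tumor"]], dim(model$labels))
  ti <- if (any(target)) temperature_indexes(temp, target) else c(T50 = NA, T90 = NA)
  structure(list(temperature = temp, kappa = kappa,
                 max_healthy = maxh(kappa), limit = limit,
                 T50 = unname(ti["T50"]), T90 = unname(ti["T90"])),
            class = "thermal_result")
}

#' @export
print.thermal_result <- function(x, ...) {
  cat(sprintf("Thermal result: kappa = %.4g, max healthy T = %.2f degC, T50 = %.2f, T90 = %.2f\n",
              x$kappa, x$max_healthy, x$T50, x$T90))
  invisible(x)
}

#' Write a temperature volume as NIfTI (float32, degC)
#' @param result a `thermal_result`.
#' @param path output path.
#' @param model the [tissue_model()] supplying the spacing.
#' @export
write_temperature <- function(result, path, model) {
  tvol <- result$temperature
  tvol[is.na(tvol)] <- 0
  attr(tvol, "pixdim") <- model$spacing
  RNifti::writeNifti(RNifti::asNifti(tvol, datatype = "float"), path)
  invisible(path)
}
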