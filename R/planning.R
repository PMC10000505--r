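# Multi-frequency SAR treatment planning: SAR assembly, 5 g mass averaging,
# evaluation masks with the 20 mm surface exclusion, the hot-to-cold spot
# quotient, and steering-parameter optimization.

#' Assemble the multi-frequency SAR distribution
#'
#' SAR = sum_f (sigma_f / 2 rho) |sum_c chi_fc E_fc|^2: coherent channel
#' superposition within each frequency, incoherent across frequencies.
#'
#' @param fields nested list `fields[[f]][[c]]` of complex 4-D field arrays.
#' @param chi complex steering matrix, n_freq x n_channel.
#' @param model a [tissue_model()].
#' @param frequencies frequency values matching the rows of `chi`, Hz.
#' @param props optional list of cached [lookup_properties()] per frequency.
#' @return 3-D SAR array, W/kg (zero where sigma = 0).
#' @export
assemble_sar <- function(fields, chi, model, frequencies, props = NULL) {
  chi <- matrix(chi, nrow = length(fields))
  nf <- length(fields)
  dm <- dim(model$labels)
  n <- prod(dm)
  sar <- numeric(n)
  for (fi in seq_len(nf)) {
    nc <- length(fields[[fi]])
    if (ncol(chi) != nc) stop("mismatched channel count")
    pf <- if (is.null(props)) lookup_properties(model, frequencies[fi]) else props[[fi]]
    tot <- NULL
    for (ci in seq_len(nc)) {
      contrib <- chi[fi, ci] * fields[[fi]][[ci]]
      tot <- if (is.null(tot)) contrib else tot + contrib
    }
    e2 <- Mod(tot[seq_len(n)])^2 + Mod(tot[n + seq_len(n)])^2 +
      Mod(tot[2L * n + seq_len(n)])^2
    sar <- sar + 0.5 * as.vector(pf$sigma) / as.vector(pf$rho) * e2
  }
  array(sar, dm)
}

# Kernel half-width (voxels) per voxel such that the in-mask tissue mass of
# the centered cube reaches target_mass kg; shared by SAR and field averaging.
kernel_radius_map <- function(rho, mask, spacing, target_mass = 0.005,
                              max_halfwidth = 10L) {
  vox_m3 <- prod(spacing) * 1e-9
  mvol <- rho * vox_m3 * mask
  if (sum(mvol) < target_mass) stop("total mask mass below the averaging mass")
  rmap <- array(NA_integer_, dim(rho))
  pend <- mask
  for (r in 0:max_halfwidth) {
    msum <- box_sum(mvol, r)
    done <- pend & msum >= target_mass
    rmap[done] <- r
    pend <- pend & !done
    if (!any(pend)) break
  }
  if (any(pend)) rmap[pend] <- max_halfwidth
  list(rmap = rmap, mvol = mvol)
}

#' 5 g mass-averaged SAR
#'
#' Smooths a SAR distribution with a variable cubic kernel grown in whole
#' voxel shells until the tissue mass inside (restricted to the patient mask)
#' reaches 5 g; voxels outside the mask contribute nothing. Surface voxels
#' therefore average over a one-sided, larger neighborhood.
#'
#' @param sar 3-D SAR array, W/kg.
#' @param rho 3-D density array, kg/m^3.
#' @param mask logical patient mask.
#' @param spacing voxel spacing, mm.
#' @param target_mass averaging mass, kg (default 0.005).
#' @return 3-D averaged SAR (zero outside the mask).
#' @export
mass_average_5g <- function(sar, rho, mask, spacing, target_mass = 0.005,
                            max_halfwidth = 10L) {
  kr <- kernel_radius_map(rho, mask, spacing, target_mass, max_halfwidth)
  out <- array(0, dim(sar))
  svol <- sar * kr$mvol
  for (r in sort(unique(kr$rmap[mask]))) {
    sel <- !is.na(kr$rmap) & kr$rmap == r & mask
    num <- box_sum(svol, r); den <- box_sum(kr$mvol, r)
    out[sel] <- num[sel] / den[sel]
  }
  out
}

# Component-wise complex 5 g averaging of a vector field (same kernels).
mass_average_field <- function(E, rho, mask, spacing, target_mass = 0.005,
                               max_halfwidth = 10L) {
  kr <- kernel_radius_map(rho, mask, spacing, target_mass, max_halfwidth)
  dm <- dim(E)[1:3]
  out <- array(0i, dim(E))
  radii <- sort(unique(kr$rmap[mask]))
  for (comp in 1:3) {
    Ec <- array(E[, , , comp], dm)
    numR <- Re(Ec) * kr$mvol; numI <- Im(Ec) * kr$mvol
    for (r in radii) {
      sel <- !is.na(kr$rmap) & kr$rmap == r & mask
      den <- box_sum(kr$mvol, r)
      out[, , , comp][sel] <- complex(real = box_sum(numR, r)[sel],
                                      imaginary = box_sum(numI, r)[sel]) / den[sel]
    }
  }
  attributes(out) <- attributes(E)
  out
}

#' Build the treatment-planning evaluation masks
#'
#' Target mask T (tumor voxels) and remaining-tissue mask R: the patient
#' volume minus the target minus the first `exclusion_mm` of tissue adjacent
#' to the water bolus or air (Euclidean distance transform from the
#' non-patient region), which models the convective cooling of the surface
#' layer. The healthy-tissue percentile is tied to the target percentile by
#' q = p |T| / |R|.
#'
#' @param model a [tissue_model()].
#' @param p target percentile, percent (0 < p <= 100).
#' @param exclusion_mm surface exclusion depth, mm (default 20).
#' @return object of class `mask_set`: logical arrays `target`, `remaining`,
#'   `patient`, depth map, `p`, `q`, and voxel volumes.
#' @export
build_evaluation_masks <- function(model, p = 50, exclusion_mm = 20) {
  stopifnot(p > 0, p <= 100)
  target <- array(model$labels == TISSUE_LABELS[["tumor"]], dim(model$labels))
  if (!any(target)) stop("no target (tumor) label present")
  patient <- patient_mask(model)
  depth <- distance_transform(!patient, model$spacing)
  remaining <- patient & !target & depth > exclusion_mm
  if (!any(remaining)) stop("remaining mask empty after surface exclusion")
  q <- p * sum(target) / sum(remaining)
  vol_ml <- prod(model$spacing) / 1000
  structure(list(target = target, remaining = remaining, patient = patient,
                 depth = depth, p = p, q = q,
                 target_ml = sum(target) * vol_ml,
                 remaining_ml = sum(remaining) * vol_ml),
            class = "mask_set")
}

#' @export
print.mask_set <- function(x, ...) {
  cat(sprintf("Masks: target %.1f mL, remaining %.1f mL, p = %g%%, q = %.2f%%\n",
              x$target_ml, x$remaining_ml, x$p, x$q))
  invisible(x)
}

# Mass-weighted tail mean: lowest (side = "low") or highest (side = "high")
# fraction `pct` percent of the distribution, nearest-rank on cumulative mass.
tail_mean <- function(values, weights, pct, side = c("low", "high")) {
  side <- match.arg(side)
  o <- order(values, decreasing = (side == "high"))
  v <- values[o]; w <- weights[o]
  cw <- cumsum(w)
  k <- which(cw >= pct / 100 * sum(w))[1L]
  sum(v[seq_len(k)] * w[seq_len(k)]) / cw[k]
}

#' Hot-to-cold spot quotient
#'
#' HCQ = mean SAR in the highest q percentile of remaining healthy tissue
#' divided by the mean SAR in the lowest p percentile of the target.
#' Percentiles are nearest-rank on cumulative voxel mass (voxels weighted by
#' their mass). Lower is better; a uniform distribution gives 1.
#'
#' @param sar (mass-averaged) 3-D SAR array.
#' @param masks a [build_evaluation_masks()] result.
#' @param rho optional density array for mass weighting (volume weights if
#'   omitted).
#' @return list with `hcq`, `sar_target_low`, `sar_remaining_high`.
#' @export
hcq <- function(sar, masks, rho = NULL) {
  wt <- if (is.null(rho)) array(1, dim(sar)) else rho
  st <- sar[masks$target]; wtt <- wt[masks$target]
  sr <- sar[masks$remaining]; wtr <- wt[masks$remaining]
  if (all(st <= 0)) stop("zero target SAR: HCQ unbounded")
  low <- tail_mean(st, wtt, masks$p, "low")
  high <- tail_mean(sr, wtr, masks$q, "high")
  list(hcq = high / low, sar_target_low = low, sar_remaining_high = high)
}

# Per-frequency covariance of the channel fields over a voxel set:
# A = sum_x w(x) sigma(x)/(2 rho(x)) E(x)^H E(x), E(x) the 3 x nc matrix of
# channel fields. Returns nc x nc Hermitian.
steering_covariance <- function(fields_f, coef, idx, n) {
  sel <- c(idx, idx + n, idx + 2L * n)
  Emat <- vapply(fields_f, function(E) E[sel], complex(length(sel)))
  cf <- rep(coef[idx], 3L)
  A <- t(Conj(Emat * cf)) %*% Emat
  (A + t(Conj(A))) / 2
}

#' Optimize multi-frequency steering parameters by iterative time reversal
#'
#' Minimizes the HCQ over the per-channel, per-frequency complex steering
#' weights. The scheme alternates between (a) identifying the current
#' cold-spot (lowest-p target) and hot-spot (highest-q healthy) voxel sets
#' from the mass-averaged SAR of the incumbent steering, and (b) solving, per
#' frequency, the generalized Rayleigh quotient maximizing cold-spot SAR
#' against hot-spot SAR via the dominant generalized eigenvector of the two
#' channel-covariance matrices, then re-allocating power across frequencies
#' toward those with the better single-frequency quotient. Iteration is
#' monotone (the best steering seen is kept) and stops at a fixed point.
#' Equal-phase uniform steering and `n_random` random steerings are evaluated
#' as competing initializations; the returned plan is never worse than any of
#' them.
#'
#' @param fields nested list `fields[[f]][[c]]` of complex field arrays.
#' @param model a [tissue_model()].
#' @param masks a [build_evaluation_masks()] result.
#' @param frequencies frequency values, Hz.
#' @param seed integer seed for the random initializations.
#' @param n_random number of random competitor steerings (default 200).
#' @param mass_average evaluate HCQ on 5 g averaged SAR (default TRUE).
#' @param maxit,tol fixed-point iteration controls.
#' @return object of class `hcq_plan`: `chi` (n_freq x n_channel complex,
#'   unit total power), `hcq`, `sar` (averaged), `power_table` (percent),
#'   `trajectory`.
#' @export
optimize_steering <- function(fields, model, masks, frequencies,
                              seed = 1L, n_random = 200L, mass_average = TRUE,
                              maxit = 50L, tol = 1e-4) {
  nf <- length(fields); nc <- length(fields[[1L]])
  dm <- dim(model$labels); n <- prod(dm)
  props <- lapply(frequencies, function(f) lookup_properties(model, f))
  rho <- props[[1L]]$rho
  if (any(!is.finite(unlist(lapply(fields, function(ff) {
    vapply(ff, function(E) all(is.finite(Re(E))) && all(is.finite(Im(E))), logical(1))
  }))))) stop("non-finite fields")
  evalchi <- function(chi) {
    sar <- assemble_sar(fields, chi, model, frequencies, props)
    sa <- if (mass_average) {
      mass_average_5g(sar, rho, masks$patient, model$spacing)
    } else sar
    list(hcq = hcq(sa, masks, rho)$hcq, sar = sa)
  }
  normalize <- function(chi) chi / sqrt(sum(Mod(chi)^2))
  # competing initializations
  chi_unif <- normalize(matrix(1 + 0i, nf, nc))
  best_chi <- chi_unif
  best <- evalchi(chi_unif)
  set.seed(as.integer(seed))
  for (r in seq_len(n_random)) {
    chi_r <- normalize(matrix(complex(real = stats::rnorm(nf * nc),
                                      imaginary = stats::rnorm(nf * nc)), nf, nc))
    er <- evalchi(chi_r)
    if (er$hcq < best$hcq) { best <- er; best_chi <- chi_r }
  }
  traj <- best$hcq
  cur_chi <- best_chi; cur <- best
  for (it in seq_len(maxit)) {
    # tails of the incumbent SAR
    st <- cur$sar[masks$target]
    thr_t <- sort(st)[max(1L, ceiling(masks$p / 100 * length(st)))]
    cold <- which(as.vector(masks$target) & as.vector(cur$sar) <= thr_t)
    sr <- cur$sar[masks$remaining]
    thr_r <- sort(sr, decreasing = TRUE)[max(1L, ceiling(masks$q / 100 * length(sr)))]
    hot <- which(as.vector(masks$remaining) & as.vector(cur$sar) >= thr_r)
    dirs <- matrix(0i, nf, nc)
    fq <- numeric(nf)
    for (fi in seq_len(nf)) {
      coef <- 0.5 * as.vector(props[[fi]]$sigma) / as.vector(props[[fi]]$rho)
      A <- steering_covariance(fields[[fi]], coef, cold, n)
      B <- steering_covariance(fields[[fi]], coef, hot, n)
      B <- B + diag(max(Re(diag(B)), 1e-30) * 1e-9, nc)
      ev <- eigen(solve(B, A))
      v <- ev$vectors[, which.max(Re(ev$values))]
      dirs[fi, ] <- v / sqrt(sum(Mod(v)^2))
      # single-frequency quotient for the reweighting
      chi_f <- matrix(0i, nf, nc); chi_f[fi, ] <- dirs[fi, ]
      fq[fi] <- evalchi(chi_f)$hcq
    }
    cands <- list(
      sweep(dirs, 1L, 1 / fq, "*"),
      dirs,
      sweep(dirs, 1L, sqrt(rowSums(Mod(cur_chi)^2)) + 1e-12, "*")
    )
    improved <- FALSE
    for (cand in cands) {
      cc <- normalize(cand)
      ec <- evalchi(cc)
      if (ec$hcq < cur$hcq - 0) { cur <- ec; cur_chi <- cc; improved <- TRUE }
    }
    traj <- c(traj, cur$hcq)
    if (cur$hcq < best$hcq) { best <- cur; best_chi <- cur_chi }
    delta <- traj[length(traj) - 1L] - traj[length(traj)]
    if (!improved || delta < tol) break
  }
  chi <- normalize(best_chi)
  power <- 100 * Mod(chi)^2
  dimnames(power) <- list(paste0(signif(frequencies / 1e6, 3), "MHz"),
                          paste0("ch", seq_len(nc)))
  structure(list(chi = chi, hcq = best$hcq, sar = best$sar,
                 power_table = t(power), frequencies = frequencies,
                 trajectory = traj,
                 sar_stats = hcq(best$sar, masks, rho)),
            class = "hcq_plan")
}

#' @export
print.hcq_plan <- function(x, ...) {
  cat(sprintf("Treatment plan: HCQ = %.4f over %d channels x %d frequencies\n",
              x$hcq, nrow(x$power_table), ncol(x$power_table)))
  invisible(x)
}

#' @export
summary.hcq_plan <- function(object, ...) {
  print(object)
  cat("Power fractions [%]:\n")
  tab <- round(cbind(object$power_table,
                     `antenna total` = rowSums(object$power_table)))
  print(tab)
  cat("Frequency totals:", round(colSums(object$power_table)), "\n")
  invisible(object)
}

#' Per-frequency totals of a per-channel power table
#'
#' Sums the per-channel percent power fractions of a plan (columns =
#' frequencies), as used for the power accounting of a steering solution.
#' @param power_table numeric matrix, channels x frequencies, percent.
#' @return named numeric vector of per-frequency totals (percent).
#' @export
power_frequency_totals <- function(power_table) {
  colSums(as.matrix(power_table))
}
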