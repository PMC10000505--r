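# Validation of approximated SAR distributions against reference ones:
# relative distribution error and hot-/cold-spot mask overlap, plus the
# patch-location error sweep.

#' Compare an approximated SAR distribution to a reference
#'
#' Both distributions are normalized to unit mean over the evaluation domain
#' (remaining + target), then compared through the mean relative absolute
#' difference (distribution error) and through the fractional overlap of the
#' hot-spot masks (highest-q percentile of remaining tissue) and cold-spot
#' masks (lowest-p percentile of target) derived independently from each
#' distribution. The mask metrics are invariant to monotone rescaling of
#' either SAR.
#'
#' @param sar_ref,sar_approx 3-D SAR arrays on one lattice (already
#'   mass-averaged consistently).
#' @param masks a [build_evaluation_masks()] result.
#' @return object of class `sar_comparison`: `dis`, `eta_hot`, `eta_cold`,
#'   mask volumes (voxels), `n_excluded`.
#' @export
sar_comparison_metrics <- function(sar_ref, sar_approx, masks) {
  stopifnot(identical(dim(sar_ref), dim(sar_approx)))
  dom <- masks$remaining | masks$target
  nrm <- function(s) s / mean(s[dom])
  a <- nrm(sar_ref); b <- nrm(sar_approx)
  ref <- a[dom]; app <- b[dom]
  ok <- ref > .Machine$double.eps
  dis <- mean(abs(ref[ok] - app[ok]) / ref[ok])
  spot_masks <- function(s) {
    sr <- s[masks$remaining]
    thr_h <- sort(sr, decreasing = TRUE)[max(1L, ceiling(masks$q / 100 * length(sr)))]
    hot <- masks$remaining & s >= thr_h
    st <- s[masks$target]
    thr_c <- sort(st)[max(1L, ceiling(masks$p / 100 * length(st)))]
    cold <- masks$target & s <= thr_c
    list(hot = hot, cold = cold)
  }
  mr <- spot_masks(a); ma <- spot_masks(b)
  structure(list(
    dis = dis,
    eta_hot = sum(mr$hot & ma$hot) / sum(mr$hot),
    eta_cold = sum(mr$cold & ma$cold) / sum(mr$cold),
    hot_voxels = sum(mr$hot), cold_voxels = sum(mr$cold),
    n_excluded = sum(!ok)),
    class = "sar_comparison")
}

#' @export
print.sar_comparison <- function(x, ...) {
  cat(sprintf("SAR comparison: eps_DIS %.1f%%, hot-spot overlap %.0f%%, cold-spot overlap %.0f%%\n",
              100 * x$dis, 100 * x$eta_hot, 100 * x$eta_cold))
  invisible(x)
}

#' Interpolation-error sweep across a patch
#'
#' Reproduces the single-antenna sensitivity analysis: a series of query
#' locations inside a patch at increasing distance from a simulated grid
#' node (step 0 sits on the node, the last step near the far edge), each
#' interpolated from the bank and compared to a direct oracle evaluation by
#' the four field-error metrics, per frequency.
#'
#' @param bank an [build_interpolation_bank()] result.
#' @param model the [tissue_model()] the bank was built on.
#' @param masks evaluation [build_evaluation_masks()] (mask M = remaining +
#'   target).
#' @param patch triangle row index into `bank$grid$triangles`; default: the
#'   largest-area patch (worst case).
#' @param n_steps number of sweep locations (default 5).
#' @param mass_average forwarded to [field_error_metrics()].
#' @return data frame with one row per (step, frequency): the step fraction,
#'   frequency, and the four error fractions.
#' @export
location_sweep_report <- function(bank, model, masks, patch = NULL,
                                  n_steps = 5L, mass_average = TRUE) {
  grid <- bank$grid
  tris <- grid$triangles
  if (is.null(patch)) {
    areas <- apply(tris, 1L, function(tr) {
      P <- grid$points[tr, ]
      vnorm(cross3(P[2L, ] - P[1L, ], P[3L, ] - P[1L, ])) / 2
    })
    patch <- which.max(areas)
  }
  tr <- tris[patch, ]
  # sweep from corner 1 toward the midpoint of the opposite edge
  u <- cbind(sin(grid$theta) * cos(grid$phi), sin(grid$theta) * sin(grid$phi),
             cos(grid$theta))
  target_dir <- (u[tr[2L], ] + u[tr[3L], ]) / 2
  out <- NULL
  dom <- masks$remaining | masks$target
  for (s in seq_len(n_steps)) {
    frac <- (s - 1) / (n_steps - 1) * 0.9
    d <- unit((1 - frac) * u[tr[1L], ] + frac * target_dir)
    th <- acos(clamp(d[3L], -1, 1)); ph <- atan2(d[2L], d[1L]) %% (2 * pi)
    pose <- antenna_frame(grid$ellipsoid, th, ph)
    for (f in bank$frequencies) {
      Eint <- interpolate_antenna_field(bank, th, ph, f)
      Esim <- oracle_antenna_field(model, pose, f)
      err <- field_error_metrics(Esim, Eint, dom, pose$U, model,
                                 mass_average = mass_average)
      out <- rbind(out, data.frame(step = s - 1L, fraction = frac,
                                   frequency = f, dis = err$dis,
                                   abs = err$abs, ang = err$ang,
                                   dir = err$dir))
    }
  }
  out
}
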