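# Global antenna-arrangement optimization: constrained random search over the
# bolus surface followed by sorted local refinement with early stopping.

#' Antenna arrangement
#'
#' @param theta,phi per-channel surface coordinates, radians.
#' @param e bolus [ellipsoid()].
#' @param r antenna clearance radius, mm.
#' @param eyes optional eye exclusion discs (see [clearance_constraints()]).
#' @return object of class `arrangement` with poses and feasibility flags.
#' @export
arrangement <- function(theta, phi, e, r = SGBT_CLEARANCE_RADIUS, eyes = NULL) {
  poses <- lapply(seq_along(theta), function(i) antenna_frame(e, theta[i], phi[i]))
  cons <- clearance_constraints(poses, r = r, eyes = eyes)
  structure(list(theta = theta, phi = phi, poses = poses, nc = length(theta),
                 constraints = cons, feasible = cons$feasible, r = r,
                 eyes = eyes, ellipsoid = e),
            class = "arrangement")
}

#' @export
print.arrangement <- function(x, ...) {
  cat(sprintf("Arrangement: %d channels, %s\n", x$nc,
              if (x$feasible) "feasible" else "INFEASIBLE"))
  invisible(x)
}

#' Sample feasible random arrangements (random-search stage)
#'
#' Draws `n` arrangements of `nc` antennas uniformly (by surface area) over
#' the available grid surface, rejecting draws that violate the pairwise
#' clearance or eye constraints. The default number of candidates follows
#' n_r = round(n_patches / nc), with n_patches the triangle count of the
#' interpolation grid: denser arrays carry more semantic redundancy, so fewer
#' qualitatively distinct starts are needed.
#'
#' @param grid a [spread_surface_grid()] result (supplies surface + patches).
#' @param nc number of channels (>= 1).
#' @param r clearance radius, mm.
#' @param eyes optional eye discs.
#' @param seed integer seed.
#' @param n number of arrangements (default round(n_patches / nc)).
#' @param max_attempts rejection-sampling cap per arrangement.
#' @return list of feasible `arrangement` objects of length `n`.
#' @export
sample_random_arrangements <- function(grid, nc, r = SGBT_CLEARANCE_RADIUS,
                                       eyes = NULL, seed = 1L, n = NULL,
                                       max_attempts = 200L) {
  stopifnot(nc >= 1L)
  e <- grid$ellipsoid
  n <- n %||% max(1L, round(nrow(grid$triangles) / nc))
  set.seed(as.integer(seed))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (att in seq_len(max_attempts)) {
      co <- sample_surface_uniform(e, nc, grid$theta_max)
      arr <- arrangement(co[, 1L], co[, 2L], e, r = r, eyes = eyes)
      if (arr$feasible) { out[[i]] <- arr; ok <- TRUE; break }
    }
    if (!ok) stop("could not draw a feasible arrangement for nc = ", nc,
                  " (surface too crowded)")
  }
  out
}

#' Interpolated HCQ of an arrangement
#'
#' Full evaluation pipeline of the array-design cost function: interpolate
#' each channel's field from the bank at every frequency, correct the array
#' for mutual coupling (K propagations), optimize the steering parameters,
#' and return the achieved HCQ. Pure function of its inputs and the seed.
#'
#' @param arr an [arrangement()].
#' @param bank an [build_interpolation_bank()] result.
#' @param coupling a `coupling_model` (or NULL to skip the correction).
#' @param model,masks planning inputs.
#' @param seed seed forwarded to the steering optimizer.
#' @param K coupling propagation count override.
#' @param ... further arguments for [optimize_steering()] (e.g. `n_random`).
#' @return the arrangement with fields `hcq` and `plan` attached.
#' @export
evaluate_arrangement <- function(arr, bank, coupling, model, masks,
                                 seed = 1L, K = NULL, ...) {
  freqs <- bank$frequencies
  fields <- vector("list", length(freqs))
  for (fi in seq_along(freqs)) {
    ch <- lapply(seq_len(arr$nc), function(ci) {
      interpolate_antenna_field(bank, arr$theta[ci], arr$phi[ci], freqs[fi])
    })
    if (!is.null(coupling) && arr$nc > 1L) {
      ch <- apply_array_coupling(ch, arr$poses, coupling, K = K)
    }
    fields[[fi]] <- ch
  }
  plan <- optimize_steering(fields, model, masks, freqs, seed = seed, ...)
  arr$hcq <- plan$hcq
  arr$plan <- plan
  arr
}

#' Sorted local refinement with early stopping (design stage)
#'
#' Sorts the evaluated random candidates by ascending HCQ and applies a
#' constrained local refinement (finite-difference quasi-Newton on the
#' (theta, phi) coordinates with a quadratic penalty on clearance and eye
#' constraint violations) to each in turn, stopping as soon as a candidate
#' refines to a worse HCQ than the best refined value so far. Refinement is
#' monotone: the best feasible point evaluated during the search is returned
#' for each candidate, so a refined HCQ never exceeds its unrefined value.
#'
#' @param candidates list of evaluated `arrangement`s (field `hcq` present).
#' @param bank,coupling,model,masks evaluation-pipeline inputs.
#' @param seed seed for the steering optimizer.
#' @param step_deg finite-difference step, degrees (default 0.5).
#' @param maxit refiner iteration cap per candidate.
#' @param ... forwarded to [evaluate_arrangement()].
#' @return object of class `design_result`: `best` (refined arrangement),
#'   `refined` (per-candidate unrefined/refined HCQ), `n_candidates`.
#' @export
refine_and_select <- function(candidates, bank, coupling, model, masks,
                              seed = 1L, step_deg = 0.5, maxit = 8L, ...) {
  stopifnot(length(candidates) >= 1L)
  hc <- vapply(candidates, function(a) a$hcq %||% NA_real_, numeric(1))
  if (anyNA(hc)) stop("all candidates must be evaluated first")
  ord <- order(hc)
  e <- candidates[[1L]]$ellipsoid
  r <- candidates[[1L]]$r; eyes <- candidates[[1L]]$eyes
  refine_one <- function(arr) {
    nc <- arr$nc
    best_env <- new.env()
    best_env$hcq <- arr$hcq; best_env$arr <- arr
    objective <- function(x) {
      th <- clamp(x[seq_len(nc)], 1e-3, bank$grid$theta_max)
      ph <- x[nc + seq_len(nc)]
      a <- tryCatch(arrangement(th, ph, e, r = r, eyes = eyes),
                    error = function(err) NULL)
      if (is.null(a)) return(best_env$hcq + 10)
      viol <- -c(a$constraints$pair[upper.tri(a$constraints$pair)],
                 a$constraints$eye)
      pen <- sum(pmax(viol / 10, 0)^2, na.rm = TRUE)
      a <- evaluate_arrangement(a, bank, coupling, model, masks, seed = seed, ...)
      if (a$feasible && a$hcq < best_env$hcq) {
        best_env$hcq <- a$hcq; best_env$arr <- a
      }
      a$hcq + pen
    }
    x0 <- c(arr$theta, arr$phi)
    step <- step_deg * pi / 180
    res <- tryCatch(
      stats::optim(x0, objective, method = "L-BFGS-B",
                   lower = c(rep(1e-3, nc), rep(-Inf, nc)),
                   upper = c(rep(bank$grid$theta_max, nc), rep(Inf, nc)),
                   control = list(maxit = maxit, ndeps = rep(step, 2L * nc))),
      error = function(err) NULL)
    if (is.null(res)) warning("refiner divergence; keeping unrefined candidate")
    best_env$arr
  }
  best_ref <- NULL
  log <- data.frame(candidate = integer(0), unrefined = numeric(0),
                    refined = numeric(0))
  for (k in ord) {
    ref <- refine_one(candidates[[k]])
    log <- rbind(log, data.frame(candidate = k,
                                 unrefined = candidates[[k]]$hcq,
                                 refined = ref$hcq))
    if (is.null(best_ref) || ref$hcq < best_ref$hcq) {
      best_ref <- ref
    } else {
      break  # refined HCQ got worse than the best refined so far
    }
  }
  structure(list(best = best_ref, refined = log,
                 n_candidates = length(candidates),
                 n_refined = nrow(log), seed = seed),
            class = "design_result")
}

#' @export
print.design_result <- function(x, ...) {
  cat(sprintf("Design result: best HCQ = %.4f (%d channels); refined %d of %d candidates\n",
              x$best$hcq, x$best$nc, x$n_refined, x$n_candidates))
  invisible(x)
}

#' End-to-end applicator design for a given array size
#'
#' Convenience driver: random-search candidates (Eq.-style count
#' round(n_patches / nc)), evaluation of each, sorted local refinement with
#' early stopping.
#'
#' @inheritParams sample_random_arrangements
#' @inheritParams refine_and_select
#' @param n_candidates override for the random-search size.
#' @export
design_applicator <- function(bank, coupling, model, masks, nc,
                              r = SGBT_CLEARANCE_RADIUS, eyes = NULL,
                              seed = 1L, n_candidates = NULL, ...) {
  cands <- sample_random_arrangements(bank$grid, nc, r = r, eyes = eyes,
                                      seed = seed, n = n_candidates)
  cands <- lapply(cands, evaluate_arrangement, bank = bank, coupling = coupling,
                  model = model, masks = masks, seed = seed, ...)
  refine_and_select(cands, bank, coupling, model, masks, seed = seed, ...)
}
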