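# Array mutual-coupling model: fit a complex coupling coefficient from pair
# experiments and correct individual antenna fields for re-radiation.

#' Projection of an impinging field on a passive antenna's polarization axis
#'
#' Samples the active antenna's field (trilinear) at the passive antenna's
#' phase center O' = O + 14 mm W and projects it onto the passive element's
#' polarization axis U.
#'
#' @param E_active complex 4-D field array with lattice attributes.
#' @param passive an [antenna_frame()] pose.
#' @return complex scalar e_AP.
#' @export
project_coupling_drive <- function(E_active, passive) {
  sp <- attr(E_active, "spacing"); og <- attr(E_active, "origin")
  v <- trilinear_sample(E_active, matrix(passive$O_phase, 1L), sp, og)
  if ((attr(v, "outside") %||% 0) > 0) {
    stop("passive phase center lies outside the field lattice")
  }
  drop(v %*% passive$U)
}

#' Coupling factor of a pair experiment by decorrelation
#'
#' Least-squares complex scalar k fitting the remainder E_AP - E_A onto the
#' passive antenna's field over the domain M:
#' k = sum(conj(E_P) . (E_AP - E_A)) / sum(conj(E_P) . E_P).
#'
#' @param E_A,E_P,E_AP complex 4-D field arrays on one lattice.
#' @param mask optional logical 3-D domain M (default: everywhere).
#' @return complex scalar k_AP.
#' @export
estimate_k_by_decorrelation <- function(E_A, E_P, E_AP, mask = NULL) {
  n <- prod(dim(E_A)[1:3])
  idx <- if (is.null(mask)) seq_len(n) else which(as.vector(mask))
  sel <- c(idx, idx + n, idx + 2L * n)
  ep <- E_P[sel]
  den <- sum(Conj(ep) * ep)
  if (Mod(den) < .Machine$double.eps) stop("passive field has zero energy on M")
  sum(Conj(ep) * (E_AP[sel] - E_A[sel])) / den
}

#' Fit the complex coupling coefficient c from pair experiments
#'
#' Complex least-squares slope through the origin of k = c e over a set of
#' (e_AP, k_AP) pairs, with the complex correlation coefficient of the fit.
#'
#' @param e complex vector of polarization-projected drives e_AP.
#' @param k complex vector of decorrelation-estimated factors k_AP.
#' @param f frequency the pairs belong to (stored, not used in the fit).
#' @param K propagation count stored with the model (default 3).
#' @return object of class `coupling_model` with fields `c`, `K`,
#'   `n_pairs`, `residual`, `correlation`, `frequency`.
#' @export
fit_coupling_coefficient <- function(e, k, f = NA_real_, K = 3L) {
  stopifnot(length(e) == length(k), length(e) >= 1L)
  if (all(Mod(e) < .Machine$double.eps)) stop("all drives are zero: cannot fit c")
  den <- sum(Conj(e) * e)
  cc <- sum(Conj(e) * k) / den
  res <- sqrt(mean(Mod(k - cc * e)^2))
  corr <- if (length(e) > 1L) {
    Mod(sum(Conj(e - mean(e)) * (k - mean(k)))) /
      sqrt(sum(Mod(e - mean(e))^2) * sum(Mod(k - mean(k))^2))
  } else NA_real_
  structure(list(c = cc, K = as.integer(K), n_pairs = length(e),
                 residual = res, correlation = corr, frequency = f),
            class = "coupling_model")
}

#' @export
print.coupling_model <- function(x, ...) {
  cat(sprintf("Coupling model: c = %.3g%+.3gi (K = %d, %d pairs, r = %.3f)\n",
              Re(x$c), Im(x$c), x$K, x$n_pairs,
              if (is.na(x$correlation)) NA else x$correlation))
  invisible(x)
}

#' Fit a per-frequency coupling model from seeded oracle pair experiments
#'
#' Generates `n_pairs` random passive poses over the bolus surface (uniform
#' area, with random rotation of the polarization axis emulated by random
#' azimuth), synthesizes each pair experiment with the field oracle, and fits
#' c by complex least squares.
#'
#' @param model spherical-phantom [tissue_model()].
#' @param e bolus [ellipsoid()] the antennas sit on.
#' @param f frequency, Hz.
#' @param c_true ground-truth coupling constant used by the oracle.
#' @param n_pairs number of random pairs (default 30).
#' @param noise relative noise amplitude of the pair synthesis.
#' @param seed integer seed.
#' @return a `coupling_model` with the fitted `c` plus `pairs` diagnostics.
#' @export
calibrate_coupling <- function(model, e, f, c_true, n_pairs = 30L,
                               noise = 0, seed = 1L, K = 3L) {
  props <- lookup_properties(model, f)
  set.seed(as.integer(seed))
  co_a <- sample_surface_uniform(e, 1L)
  active <- antenna_frame(e, co_a[1L, 1L], co_a[1L, 2L], retract = FALSE)
  co_p <- sample_surface_uniform(e, n_pairs)
  seeds <- child_seeds(seed, n_pairs)
  es <- complex(n_pairs); ks <- complex(n_pairs)
  for (i in seq_len(n_pairs)) {
    passive <- antenna_frame(e, co_p[i, 1L], co_p[i, 2L], retract = FALSE)
    pe <- oracle_pair_experiment(model, active, passive, f, c_true,
                                 noise = noise, seed = seeds[i], props = props)
    es[i] <- pe$e_AP
    ks[i] <- estimate_k_by_decorrelation(pe$EA, pe$EP, pe$EAP)
  }
  fitted <- fit_coupling_coefficient(es, ks, f = f, K = K)
  fitted$pairs <- list(e = es, k = ks)
  fitted
}

#' Correct individual array fields for mutual coupling
#'
#' Stacks the per-channel fields and applies the K-propagation coupling
#' expansion: with C the pure coupling matrix (zero diagonal, c e_ij
#' off-diagonal entries, e_ij = <U_j, E_i(O'_j)> the drive of channel i's
#' field at channel j's phase center), the corrected stack is the truncated
#' reflection series (I + C + ... + C^(K-1)) E. K = 1 returns the inputs
#' unchanged (first excitation only) and K = 2 adds the first reflection
#' E_i + sum_j c e_ij E_j; each further propagation adds one more round of
#' re-radiation, with geometrically shrinking contributions while
#' |c e| < 1.
#'
#' @param fields list of per-channel complex 4-D field arrays.
#' @param poses list of matching [antenna_frame()] poses.
#' @param coupling a `coupling_model` (fields `c`, `K`).
#' @param K optional override of the propagation count.
#' @return list of corrected field arrays.
#' @export
apply_array_coupling <- function(fields, poses, coupling, K = NULL) {
  n <- length(fields)
  if (length(poses) != n) stop("dimension mismatch between fields and poses")
  K <- K %||% coupling$K
  stopifnot(K >= 1L)
  if (K == 1L || n == 1L) return(fields)
  C <- matrix(0i, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      C[i, j] <- coupling$c * project_coupling_drive(fields[[i]], poses[[j]])
    }
  }
  Mk <- diag(1 + 0i, n)
  Cp <- diag(1 + 0i, n)
  for (p in seq_len(K - 1L)) {
    Cp <- Cp %*% C
    Mk <- Mk + Cp
  }
  out <- vector("list", n)
  for (i in seq_len(n)) {
    acc <- Mk[i, 1L] * fields[[1L]]
    for (j in seq_len(n)[-1L]) acc <- acc + Mk[i, j] * fields[[j]]
    attributes(acc) <- attributes(fields[[i]])
    out[[i]] <- acc
  }
  out
}

#' Serialize / restore a coupling model as JSON
#' @param x a `coupling_model`.
#' @param path output path.
#' @export
write_coupling_model <- function(x, path) {
  jsonlite::write_json(list(c = c(Re(x$c), Im(x$c)), K = x$K,
                            n_pairs = x$n_pairs, residual = x$residual,
                            correlation = x$correlation,
                            frequency = x$frequency),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_coupling_model
#' @export
read_coupling_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(c = complex(real = j$c[1L], imaginary = j$c[2L]),
                 K = as.integer(j$K), n_pairs = j$n_pairs,
                 residual = j$residual, correlation = j$correlation,
                 frequency = j$frequency),
            class = "coupling_model")
}
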