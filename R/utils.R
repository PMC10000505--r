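# Internal numerical helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
vnorm <- function(x) sqrt(sum(x^2))

unit <- function(x) {
  n <- vnorm(x)
  if (n < .Machine$double.eps) stop("cannot normalize zero vector")
  x / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# Row-wise cross product for n x 3 matrices.
cross3_rows <- function(a, b) {
  cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
        a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
        a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Voxel center coordinates of a lattice
#'
#' Returns an n-voxel by 3 matrix of cell-center coordinates in mm, in array
#' order (first index fastest).
#' @keywords internal
voxel_centers <- function(dim, spacing, origin) {
  idx <- arrayInd(seq_len(prod(dim)), .dim = dim)
  cbind(origin[1L] + (idx[, 1L] - 1L) * spacing[1L],
        origin[2L] + (idx[, 2L] - 1L) * spacing[2L],
        origin[3L] + (idx[, 3L] - 1L) * spacing[3L])
}

# Map points (mm) to fractional (1-based) voxel indices.
point_to_index <- function(points, spacing, origin) {
  sweep(sweep(points, 2L, origin, "-"), 2L, spacing, "/") + 1
}

#' Trilinear sampling of a scalar or vector volume
#'
#' @param vol numeric or complex array; either 3-D (scalar field) or 4-D with
#'   the last dimension of extent 3 (vector field).
#' @param points m x 3 matrix of query coordinates, mm.
#' @param spacing,origin lattice geometry, mm.
#' @param fill value used for samples outside the lattice.
#' @return For a 3-D `vol` a length-m vector; for 4-D an m x 3 matrix. The
#'   attribute `outside` carries the fraction of out-of-lattice samples.
#' @keywords internal
trilinear_sample <- function(vol, points, spacing, origin, fill = 0) {
  d <- dim(vol)
  vec <- length(d) == 4L
  dims <- if (vec) d[1:3] else d
  fi <- point_to_index(points, spacing, origin)
  i0 <- floor(fi)
  fr <- fi - i0
  ok <- i0[, 1L] >= 1 & i0[, 2L] >= 1 & i0[, 3L] >= 1 &
    i0[, 1L] <= dims[1L] - 1 & i0[, 2L] <= dims[2L] - 1 & i0[, 3L] <= dims[3L] - 1
  # Points exactly on the upper faces are pulled onto the last cell.
  hi <- !ok & fi[, 1L] >= 1 & fi[, 2L] >= 1 & fi[, 3L] >= 1 &
    fi[, 1L] <= dims[1L] & fi[, 2L] <= dims[2L] & fi[, 3L] <= dims[3L]
  if (any(hi)) {
    i0[hi, ] <- pmin(i0[hi, , drop = FALSE], rep(dims - 1L, each = sum(hi)))
    i0[hi, ] <- pmax(i0[hi, , drop = FALSE], 1)
    fr[hi, ] <- fi[hi, , drop = FALSE] - i0[hi, , drop = FALSE]
    ok <- ok | hi
  }
  m <- nrow(points)
  ncomp <- if (vec) 3L else 1L
  out <- matrix(if (is.complex(vol)) complex(real = fill) else fill, m, ncomp)
  if (any(ok)) {
    ia <- i0[ok, , drop = FALSE]
    fa <- fr[ok, , drop = FALSE]
    n12 <- dims[1L] * dims[2L]
    base <- (ia[, 1L]) + (ia[, 2L] - 1) * dims[1L] + (ia[, 3L] - 1) * n12
    offs <- expand.grid(dx = 0:1, dy = 0:1, dz = 0:1)
    for (comp in seq_len(ncomp)) {
      comp_off <- if (vec) (comp - 1L) * prod(dims) else 0L
      acc <- 0
      for (r in seq_len(8L)) {
        dx <- offs$dx[r]; dy <- offs$dy[r]; dz <- offs$dz[r]
        w <- (if (dx) fa[, 1L] else 1 - fa[, 1L]) *
          (if (dy) fa[, 2L] else 1 - fa[, 2L]) *
          (if (dz) fa[, 3L] else 1 - fa[, 3L])
        lin <- base + dx + dy * dims[1L] + dz * n12 + comp_off
        acc <- acc + w * vol[lin]
      }
      out[ok, comp] <- acc
    }
  }
  res <- if (vec) out else drop(out)
  attr(res, "outside") <- 1 - mean(ok)
  res
}

# 1-D squared Euclidean distance transform (lower envelope of parabolas),
# Felzenszwalb & Huttenlocher. f is the squared distance seed per cell.
edt_1d <- function(f, step) {
  n <- length(f)
  d <- numeric(n)
  v <- integer(n); z <- numeric(n + 1L)
  k <- 1L
  v[1L] <- 1L; z[1L] <- -Inf; z[2L] <- Inf
  s2 <- step * step
  for (q in 2:n) {
    repeat {
      p <- v[k]
      s <- ((f[q] + s2 * q * q) - (f[p] + s2 * p * p)) / (2 * s2 * (q - p))
      if (s <= z[k]) {
        k <- k - 1L
        if (k == 0L) { k <- 1L; v[1L] <- q; z[1L] <- -Inf; z[2L] <- Inf; break }
      } else {
        k <- k + 1L
        v[k] <- q; z[k] <- s; z[k + 1L] <- Inf
        break
      }
    }
  }
  k <- 1L
  for (q in seq_len(n)) {
    while (z[k + 1L] < q) k <- k + 1L
    p <- v[k]
    d[q] <- s2 * (q - p)^2 + f[p]
  }
  d
}

#' 3-D Euclidean distance transform on a voxel lattice
#'
#' Distance (mm) from every voxel to the nearest voxel where `seed` is TRUE,
#' honoring anisotropic spacing. Separable squared-distance passes.
#' @keywords internal
distance_transform <- function(seed, spacing) {
  dm <- dim(seed)
  big <- (sum(dm * spacing))^2  # exceeds any achievable squared distance
  g <- array(ifelse(seed, 0, big), dm)
  for (ax in 1:3) {
    g <- apply(g, setdiff(1:3, ax), function(col) edt_1d(col, spacing[ax]))
    # apply() returns with the processed axis first; restore order
    g <- aperm(g, order(c(ax, setdiff(1:3, ax))))
  }
  sqrt(g)
}

# Cumulative box sums: S[i,j,k] = sum of vol over [1..i,1..j,1..k].
cumsum3 <- function(vol) {
  s <- apply(vol, c(2, 3), cumsum)
  s <- apply(s, c(1, 3), cumsum); s <- aperm(s, c(2, 1, 3))
  s <- apply(s, c(1, 2), cumsum); aperm(s, c(2, 3, 1))
}

# Sum of vol over the centered cube of half-width r (voxels) around every
# voxel, with clipping at the lattice boundary.
box_sum <- function(vol, r) {
  dm <- dim(vol)
  S <- array(0, dm + 1L)
  S[-1L, -1L, -1L] <- cumsum3(vol)
  i <- seq_len(dm[1L]); j <- seq_len(dm[2L]); k <- seq_len(dm[3L])
  hi1 <- pmin(i + r, dm[1L]) + 1L; lo1 <- pmax(i - r - 1L, 0L) + 1L
  hi2 <- pmin(j + r, dm[2L]) + 1L; lo2 <- pmax(j - r - 1L, 0L) + 1L
  hi3 <- pmin(k + r, dm[3L]) + 1L; lo3 <- pmax(k - r - 1L, 0L) + 1L
  S[hi1, hi2, hi3] - S[lo1, hi2, hi3] - S[hi1, lo2, hi3] - S[hi1, hi2, lo3] +
    S[lo1, lo2, hi3] + S[lo1, hi2, lo3] + S[hi1, lo2, lo3] - S[lo1, lo2, lo3]
}

# Derive a stream of child seeds (< 2^31) from one integer seed.
child_seeds <- function(seed, n) {
  (as.integer(seed) + 1000003L * seq_len(n)) %% 2147483629L
}

wrap_angle <- function(x) {
  ((x + pi) %% (2 * pi)) - pi
}
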