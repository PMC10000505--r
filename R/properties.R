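# Tissue property table and electromagnetic material constants.

EPS0 <- 8.8541878128e-12   # vacuum permittivity, F/m
MU0 <- 1.25663706212e-6    # vacuum permeability, H/m
C0 <- 299792458            # speed of light in vacuum, m/s
ETA0 <- 376.730313668      # free-space impedance, Ohm

#' Canonical tissue label codes
#'
#' Integer codes used in label grids; 0 is always the exterior background
#' (air, or water depending on context). Every nonzero code has a row in the
#' shipped property table.
#' @export
TISSUE_LABELS <- c(
  exterior = 0L, water = 1L, skin = 2L, muscle = 3L, bone_cortical = 4L,
  csf = 5L, brain_gray = 6L, brain_white = 7L, eye = 8L, cartilage = 9L,
  pharynx_air = 10L, tumor = 11L
)

#' Load the shipped tissue property table
#'
#' Reads the versioned per-tissue dielectric and thermal property table
#' (relative permittivity and conductivity at 250/375/500 MHz, density,
#' specific heat, thermal conductivity and perfusion) distributed with the
#' package, or a user-supplied table in the same YAML layout.
#'
#' @param path optional path to an alternative YAML property file.
#' @return A list with `frequencies` (Hz) and a data frame `table` with one
#'   row per (tissue, frequency) pair.
#' @export
load_property_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "tissue_properties.yaml",
                                package = "helmetplan", mustWork = TRUE)
  raw <- yaml::read_yaml(path)
  freqs <- as.numeric(raw$frequencies_hz)
  rows <- lapply(names(raw$tissues), function(tn) {
    tt <- raw$tissues[[tn]]
    data.frame(tissue = tn, frequency = freqs,
               eps_r = as.numeric(tt$eps_r), sigma = as.numeric(tt$sigma),
               rho = tt$rho, cp = tt$cp, k_th = tt$k_th,
               perfusion = tt$perfusion, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  stopifnot(all(tab$sigma >= 0), all(tab$eps_r >= 1), all(tab$rho > 0))
  list(frequencies = freqs, table = tab, version = raw$version)
}

#' Intrinsic impedance of a lossy dielectric
#'
#' Complex intrinsic impedance eta = eta0 / sqrt(eps_r - j sigma/(omega eps0)).
#' With `mode = "lossless"` the loss term is dropped and the classic real
#' eta0/sqrt(eps_r) is returned.
#'
#' @param eps_r relative permittivity (vector ok).
#' @param sigma conductivity, S/m.
#' @param f frequency, Hz.
#' @param mode `"complex"` (default) or `"lossless"`.
#' @return complex impedance in Ohm (complex even in lossless mode).
#' @export
#' @examples
#' intrinsic_impedance(1, 0, 500e6)        # free space, 376.7 Ohm
#' intrinsic_impedance(78, 0, 500e6)       # lossless water, ~42.7 Ohm
intrinsic_impedance <- function(eps_r, sigma, f, mode = c("complex", "lossless")) {
  mode <- match.arg(mode)
  if (mode == "lossless") {
    return(as.complex(ETA0 / sqrt(eps_r)))
  }
  ec <- complex(real = eps_r, imaginary = -sigma / (2 * pi * f * EPS0))
  ETA0 / sqrt(ec)
}

# Complex relative permittivity eps_r - j sigma/(omega eps0).
complex_permittivity <- function(eps_r, sigma, f) {
  complex(real = eps_r, imaginary = -sigma / (2 * pi * f * EPS0))
}

# Complex wavenumber (rad/m), principal branch: Im < 0 so that
# exp(-j k s) decays with distance in a lossy medium.
complex_wavenumber <- function(eps_r, sigma, f) {
  (2 * pi * f / C0) * sqrt(complex_permittivity(eps_r, sigma, f))
}

#' Wavelength in a tissue at a table frequency
#'
#' Lossless wavelength c0 / (f sqrt(eps_r)) using the tabulated permittivity.
#'
#' @param tissue tissue name in the property table.
#' @param f frequency in Hz (must be in the table's frequency set).
#' @param properties optional property list from [load_property_table()].
#' @return wavelength in meters.
#' @export
tissue_wavelength <- function(tissue, f, properties = NULL) {
  props <- properties %||% load_property_table()
  row <- props$table[props$table$tissue == tissue & props$table$frequency == f, ]
  if (nrow(row) != 1L) stop("no property row for ", tissue, " at ", f, " Hz")
  C0 / (f * sqrt(row$eps_r))
}
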