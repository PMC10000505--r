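# Persistence of the main containers. Field sets are stored as an RDS
# payload with a JSON metadata sidecar; grids and plans as JSON.

#' Save / load a set of field volumes
#'
#' Stores a nested list of complex field arrays (e.g. an interpolation
#' bank's `fields`) together with lattice metadata. The payload is base R
#' serialization; a `.json` sidecar carries the lattice geometry and the
#' frequency/channel structure for interoperability.
#'
#' @param fields nested list of complex 4-D arrays.
#' @param path output `.rds` path (sidecar written next to it).
#' @param spacing,origin,frequencies lattice metadata.
#' @export
write_fieldset <- function(fields, path, spacing, origin, frequencies) {
  saveRDS(list(fields = fields, spacing = spacing, origin = origin,
               frequencies = frequencies), path)
  first <- fields[[1L]]
  if (is.list(first)) first <- first[[1L]]
  jsonlite::write_json(
    list(spacing = spacing, origin = origin, frequencies = frequencies,
         dim = dim(first)[1:3],
         n_frequencies = length(fields),
         n_channels = if (is.list(fields[[1L]])) length(fields[[1L]]) else 1L),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fieldset
#' @export
read_fieldset <- function(path) {
  readRDS(path)
}

#' Serialize a surface grid to JSON
#' @param grid a [spread_surface_grid()] result.
#' @param path output path.
#' @export
write_surface_grid <- function(grid, path) {
  jsonlite::write_json(
    list(theta = grid$theta, phi = grid$phi,
         triangles = grid$triangles, theta_max = grid$theta_max,
         max_edge = grid$max_edge, mean_edge = grid$mean_edge,
         ellipsoid = list(radii = grid$ellipsoid$radii,
                          center = grid$ellipsoid$center,
                          trim_offset = grid$ellipsoid$trim_offset)),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_surface_grid
#' @export
read_surface_grid <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  trim <- j$ellipsoid$trim_offset
  if (!length(trim)) trim <- NULL
  e <- ellipsoid(j$ellipsoid$radii, j$ellipsoid$center, trim)
  grid <- structure(list(theta = j$theta, phi = j$phi, ellipsoid = e,
                         theta_max = j$theta_max),
                    class = "surface_grid")
  triangulate_grid(grid)
}

#' Serialize a treatment plan to JSON
#'
#' Steering parameters are written as `[re, im]` pairs per (frequency,
#' channel), together with the achieved HCQ and the power table.
#' @param plan an `hcq_plan`.
#' @param path output path.
#' @export
write_plan <- function(plan, path) {
  chi <- plan$chi
  jsonlite::write_json(
    list(hcq = plan$hcq,
         frequencies = plan$frequencies,
         chi_re = Re(chi), chi_im = Im(chi),
         power_table = plan$power_table,
         sar_target_low = plan$sar_stats$sar_target_low,
         sar_remaining_high = plan$sar_stats$sar_remaining_high),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
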