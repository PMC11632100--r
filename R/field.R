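#' Scalar and vectorial optical fields
#'
#' A `ol_scalar_field` carries one complex amplitude raster `u` on a grid; a
#' `ol_vector_field` carries the three Cartesian components `ex`, `ey`, `ez`.
#' Rasters are complex matrices with `ny` rows and `nx` columns; element
#' `[iy, ix]` sits at physical position `(x[ix], y[iy])`. The vacuum
#' wavelength is stored in nanometres; all transverse coordinates are in
#' micrometres, so the wavenumber used internally is `2*pi / (wavelength/1000)`
#' in rad/um.
#'
#' @param grid An `ol_grid`.
#' @param u,ex,ey,ez Complex matrices matching the grid shape. Missing vector
#'   components default to zero.
#' @param wavelength Vacuum wavelength in nanometres.
#' @return An `ol_scalar_field` / `ol_vector_field` object.
#' @export
scalar_field <- function(grid, u, wavelength) {
  stopifnot(inherits(grid, "ol_grid"))
  u <- as_complex_raster(u, grid)
  check_wavelength(wavelength)
  structure(list(grid = grid, u = u, wavelength = wavelength),
            class = "ol_scalar_field")
}

#' @rdname scalar_field
#' @export
vector_field <- function(grid, ex, ey = NULL, ez = NULL, wavelength) {
  stopifnot(inherits(grid, "ol_grid"))
  check_wavelength(wavelength)
  z <- matrix(0 + 0i, grid$ny, grid$nx)
  ex <- as_complex_raster(ex, grid)
  ey <- if (is.null(ey)) z else as_complex_raster(ey, grid)
  ez <- if (is.null(ez)) z else as_complex_raster(ez, grid)
  structure(list(grid = grid, ex = ex, ey = ey, ez = ez, wavelength = wavelength),
            class = "ol_vector_field")
}

as_complex_raster <- function(m, grid) {
  if (is.null(dim(m)) || nrow(m) != grid$ny || ncol(m) != grid$nx)
    stop("component raster shape must match the grid (ny rows, nx cols)")
  storage.mode(m) <- "complex"
  m
}

check_wavelength <- function(wavelength) {
  if (!is.numeric(wavelength) || length(wavelength) != 1L ||
      !is.finite(wavelength) || wavelength <= 0)
    stop("'wavelength' must be a positive number (nanometres)")
}

# wavenumber in rad/um
wavenumber <- function(field_or_nm) {
  wl <- if (is.numeric(field_or_nm)) field_or_nm else field_or_nm$wavelength
  2 * pi / (wl * 1e-3)
}

wavelength_um <- function(field_or_nm) {
  wl <- if (is.numeric(field_or_nm)) field_or_nm else field_or_nm$wavelength
  wl * 1e-3
}

is_vector_field <- function(f) inherits(f, "ol_vector_field")

field_components <- function(f) {
  if (is_vector_field(f)) list(ex = f$ex, ey = f$ey, ez = f$ez) else list(u = f$u)
}

#' Total optical power carried by a field
#'
#' Power is the discrete surface integral `sum(|E|^2) * pitch_x * pitch_y`
#' over all components, in arbitrary units consistent across the package.
#'
#' @param field An `ol_scalar_field` or `ol_vector_field`.
#' @return A non-negative number.
#' @export
field_power <- function(field) {
  comps <- field_components(field)
  s <- sum(vapply(comps, function(m) sum(Mod(m)^2), numeric(1)))
  s * grid_dA(field$grid)
}

#' Intensity raster of a field
#'
#' @param field An `ol_vector_field` (or `ol_scalar_field`, for which only
#'   `"total"` makes sense).
#' @param component One of `"total"` (`|Ex|^2+|Ey|^2+|Ez|^2`), `"transverse"`
#'   (`|Ex|^2+|Ey|^2`) or `"longitudinal"` (`|Ez|^2`).
#' @return A numeric matrix on the field's grid.
#' @export
field_intensity <- function(field, component = c("total", "transverse", "longitudinal")) {
  component <- match.arg(component)
  if (!is_vector_field(field)) {
    if (component != "total") stop("scalar fields have no polarization components")
    return(Mod(field$u)^2)
  }
  switch(component,
    total        = Mod(field$ex)^2 + Mod(field$ey)^2 + Mod(field$ez)^2,
    transverse   = Mod(field$ex)^2 + Mod(field$ey)^2,
    longitudinal = Mod(field$ez)^2)
}

#' Linearly polarized Gaussian source
#'
#' Builds a transverse (`ez = 0`) Gaussian beam at its waist,
#' `E(x, y) = exp(-(x^2 + y^2) / waist^2)`, polarized along a normalized
#' Jones vector, and normalized to unit total power. The `1/e^2` intensity
#' radius of the beam equals `waist`.
#'
#' @param grid An `ol_grid`.
#' @param wavelength Vacuum wavelength in nanometres.
#' @param waist `1/e^2` intensity radius in micrometres. Defaults to a quarter
#'   of the grid half-width, which keeps the beam well contained for FFT
#'   propagation.
#' @param polarization Length-2 Jones vector (may be complex); it is
#'   normalized to unit modulus internally and must not be the zero vector.
#' @return An `ol_vector_field` of unit power.
#' @examples
#' g <- make_grid(64, 64, 1)
#' src <- gaussian_source(g, 650, waist = 8, polarization = c(1, 0))
#' abs(field_power(src) - 1) < 1e-6
#' @export
gaussian_source <- function(grid, wavelength, waist = NULL,
                            polarization = c(1, 0)) {
  stopifnot(inherits(grid, "ol_grid"))
  check_wavelength(wavelength)
  half_width <- min(grid$nx * grid$pitch[1], grid$ny * grid$pitch[2]) / 2
  if (is.null(waist)) waist <- half_width / 4
  if (!is.finite(waist) || waist <= 2 * max(grid$pitch))
    stop("waist is not resolvable: need waist > 2 * pitch")
  if (length(polarization) != 2L) stop("'polarization' must be a Jones pair")
  pol <- as.complex(polarization)
  nrm <- sqrt(sum(Mod(pol)^2))
  if (nrm == 0) stop("'polarization' must be a nonzero Jones pair")
  pol <- pol / nrm
  r2 <- outer(grid$y^2, grid$x^2, `+`)
  amp <- exp(-r2 / waist^2)
  amp <- amp / sqrt(sum(amp^2) * grid_dA(grid))  # unit power
  vector_field(grid,
               ex = amp * pol[1], ey = amp * pol[2],
               wavelength = wavelength)
}

#' @export
print.ol_vector_field <- function(x, ...) {
  cat(sprintf("<ol_vector_field> %d x %d, pitch %.4g um, lambda %.4g nm, power %.4g\n",
              x$grid$nx, x$grid$ny, x$grid$pitch[1], x$wavelength, field_power(x)))
  invisible(x)
}

#' @export
print.ol_scalar_field <- function(x, ...) {
  cat(sprintf("<ol_scalar_field> %d x %d, pitch %.4g um, lambda %.4g nm, power %.4g\n",
              x$grid$nx, x$grid$ny, x$grid$pitch[1], x$wavelength, field_power(x)))
  invisible(x)
}

#' @export
`+.ol_vector_field` <- function(e1, e2) {
  stop_if_grid_mismatch(e1$grid, e2$grid)
  if (e1$wavelength != e2$wavelength)
    stop("cannot superpose fields of different wavelengths coherently")
  vector_field(e1$grid, e1$ex + e2$ex, e1$ey + e2$ey, e1$ez + e2$ez,
               wavelength = e1$wavelength)
}

#' @export
`+.ol_scalar_field` <- function(e1, e2) {
  stop_if_grid_mismatch(e1$grid, e2$grid)
  if (e1$wavelength != e2$wavelength)
    stop("cannot superpose fields of different wavelengths coherently")
  scalar_field(e1$grid, e1$u + e2$u, wavelength = e1$wavelength)
}

# convert between scalar and vector views
scalar_component <- function(field, which = c("ex", "ey", "ez")) {
  which <- match.arg(which)
  scalar_field(field$grid, field[[which]], field$wavelength)
}
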