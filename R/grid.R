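#' Sampling grid for optical fields
#'
#' Creates the centered sampling lattice on which all fields, masks and
#' detector rasters live. Coordinates are physical, in micrometres, with x
#' increasing rightward (along matrix columns) and y increasing upward (along
#' matrix rows). The lattice is symmetric about the optical axis: for `n`
#' pixels of pitch `p` the coordinates are `(0:(n-1) - (n-1)/2) * p`.
#'
#' @param nx,ny Pixel counts along x and y. Must be at least 8.
#' @param pitch Physical pixel size in micrometres. Either a single value or
#'   a length-2 vector `c(pitch_x, pitch_y)`; anisotropic pitches arise from
#'   zoomed output windows.
#' @return An object of class `ol_grid`: a list with elements `nx`, `ny`,
#'   `pitch` (always length 2), and coordinate axes `x`, `y` (micrometres).
#' @examples
#' g <- make_grid(8, 8, 1.0)
#' g$x  # -3.5 ... 3.5
#' @export
make_grid <- function(nx, ny, pitch) {
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (length(pitch) == 1L) pitch <- c(pitch, pitch)
  if (length(pitch) != 2L || any(!is.finite(pitch)) || any(pitch <= 0))
    stop("'pitch' must be one or two positive finite numbers (micrometres)")
  if (is.na(nx) || is.na(ny) || nx < 8L || ny < 8L)
    stop("grid dimensions must be integers >= 8")
  g <- list(
    nx = nx, ny = ny, pitch = as.numeric(pitch),
    x = (seq_len(nx) - 1 - (nx - 1) / 2) * pitch[1],
    y = (seq_len(ny) - 1 - (ny - 1) / 2) * pitch[2]
  )
  class(g) <- "ol_grid"
  g
}

#' @export
print.ol_grid <- function(x, ...) {
  cat(sprintf("<ol_grid> %d x %d pixels, pitch %.4g x %.4g um, extent %.4g x %.4g um\n",
              x$nx, x$ny, x$pitch[1], x$pitch[2],
              x$nx * x$pitch[1], x$ny * x$pitch[2]))
  invisible(x)
}

#' Compare two grids for sampling equality
#'
#' Two grids are considered equal when their pixel counts and pitches match;
#' mixed-grid arithmetic is rejected throughout the package on this basis.
#'
#' @param a,b `ol_grid` objects.
#' @return `TRUE` or `FALSE`.
#' @export
grid_equal <- function(a, b) {
  stopifnot(inherits(a, "ol_grid"), inherits(b, "ol_grid"))
  a$nx == b$nx && a$ny == b$ny && isTRUE(all.equal(a$pitch, b$pitch, tolerance = 1e-12))
}

# pixel area in um^2, used for power bookkeeping
grid_dA <- function(grid) grid$pitch[1] * grid$pitch[2]

# matrices of x / y coordinates (ny rows, nx cols)
grid_xmat <- function(grid) matrix(grid$x, grid$ny, grid$nx, byrow = TRUE)
grid_ymat <- function(grid) matrix(grid$y, grid$ny, grid$nx)

stop_if_grid_mismatch <- function(a, b, what = "fields") {
  if (!grid_equal(a, b)) stop("grid mismatch: ", what, " must share pixel counts and pitch")
}

#' Wrap phase values to (-pi, pi]
#'
#' The package-wide phase convention: radians, wrapped to the half-open
#' interval (-pi, pi].
#'
#' @param x Numeric vector, matrix or array of phases in radians.
#' @return Object of the same shape with all values in (-pi, pi].
#' @export
wrap_phase <- function(x) {
  y <- -((-x + pi) %% (2 * pi) - pi)
  y
}
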