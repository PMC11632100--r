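# Free-space diffraction: scalar and vectorial Rayleigh-Sommerfeld (RS / VRS),
# their chirped z-transform zoom variants (CZT / VCZT), and Richards-Wolf
# high-NA focusing.
#
# RS is evaluated as an FFT convolution with the exact first Rayleigh-
# Sommerfeld kernel on a zero-padded grid (2x linear size), which keeps the
# computation valid for short, non-paraxial hops:
#
#   h_q(x, y; z) = (q / 2pi) * exp(1i*k*r) * (1/r - 1i*k) / r^2 ,
#   r = sqrt(x^2 + y^2 + z^2),
#
# with q = z for the transverse (scalar) kernel. The longitudinal component
# Ez is synthesized through the transversality relation of the angular
# spectrum, Ez~ = -(kx Ex~ + ky Ey~)/kz, which is the frequency-domain form
# of the x- and y-weighted kernel derivatives of the spherical wave and keeps
# the output divergence-free without truncation error. Backward propagation
# (z < 0) uses the conjugate kernel at |z|, so evanescent components are
# attenuated, never amplified.

rs_pad_size <- function(n) stats::nextn(2L * n, 2L)

# scalar radial part g(r) of the kernel and its derivative
rs_gfun <- function(r, k) exp(1i * k * r) * (1 / r - 1i * k) / r^2
rs_gprime <- function(r, k) exp(1i * k * r) * (-3 / r^4 + 3i * k / r^3 + k^2 / r^2)

# Precompute padding geometry and transfer rasters for one (grid, lambda, z).
# `which` selects kernels: "z" (scalar/transverse), "x"/"y" (Ez synthesis),
# "dz" (analytic d/dz of the scalar kernel, used by the adjoint engine).
#
# The same diffraction operator is evaluated in whichever domain samples it
# faithfully (the standard dual-domain rule): below the critical distance
# z_c = P * pitch^2 / lambda the angular-spectrum transfer exp(1i*kz*z) is
# exact and unitary, beyond it the spatial impulse response (whose chirp is
# then resolved) is used. Both are the first Rayleigh-Sommerfeld solution.
rs_prep <- function(grid, wavelength, z, which = "z") {
  px <- rs_pad_size(grid$nx); py <- rs_pad_size(grid$ny)
  ox <- (px - grid$nx) %/% 2L; oy <- (py - grid$ny) %/% 2L
  k <- wavenumber(wavelength)
  za <- abs(z)
  dA <- grid_dA(grid)

  # frequency lattice of the padded grid (fft order)
  kxv <- 2 * pi / (px * grid$pitch[1]) * c(0:(px %/% 2 - 1), -(px - px %/% 2):-1)
  kyv <- 2 * pi / (py * grid$pitch[2]) * c(0:(py %/% 2 - 1), -(py - py %/% 2):-1)
  KXf <- matrix(kxv, py, px, byrow = TRUE)
  KYf <- matrix(kyv, py, px)
  kzc <- sqrt(as.complex(k^2 - KXf^2 - KYf^2))  # +1i|kz| when evanescent

  z_crit <- min(px * grid$pitch[1]^2, py * grid$pitch[2]^2) / wavelength_um(wavelength)
  use_tf <- za <= z_crit

  if (use_tf) {
    Hf <- exp(1i * kzc * za)
    dHf <- if ("dz" %in% which) 1i * kzc * Hf else NULL
  } else {
    xp <- (seq_len(px) - 1 - floor(px / 2)) * grid$pitch[1]
    yp <- (seq_len(py) - 1 - floor(py / 2)) * grid$pitch[2]
    X <- matrix(xp, py, px, byrow = TRUE)
    Y <- matrix(yp, py, px)
    R <- sqrt(X^2 + Y^2 + za^2)
    g <- rs_gfun(R, k)
    Hf <- stats::fft(ifftshift2(za * g / (2 * pi))) * dA
    dHf <- if ("dz" %in% which)
      stats::fft(ifftshift2((g + za^2 * rs_gprime(R, k) / R) / (2 * pi))) * dA
    else NULL
  }

  # spectral factors -kq/kz for the longitudinal synthesis; kz clamped away
  # from the horizon ring, evanescent part decays through Hz itself
  kq_over_kz <- function(axis) {
    kz <- kzc
    kz[Mod(kz) < 1e-3 * k] <- 1e-3 * k
    KQ <- if (axis == "x") KXf else KYf
    -sign(z) * KQ / kz
  }
  Hz <- if (z < 0) Conj(Hf) else Hf
  H <- lapply(which, function(w) {
    switch(w,
      z  = Hz,
      x  = kq_over_kz("x") * Hz,
      y  = kq_over_kz("y") * Hz,
      dz = if (z < 0) -Conj(dHf) else dHf,
      stop("unknown kernel selector"))
  })
  names(H) <- which
  list(px = px, py = py, ox = ox, oy = oy, H = H, grid = grid,
       wavelength = wavelength, z = z)
}

rs_pad <- function(u, prep) {
  m <- matrix(0 + 0i, prep$py, prep$px)
  m[prep$oy + seq_len(prep$grid$ny), prep$ox + seq_len(prep$grid$nx)] <- u
  m
}

rs_crop <- function(m, prep) {
  m[prep$oy + seq_len(prep$grid$ny), prep$ox + seq_len(prep$grid$nx), drop = FALSE]
}

# apply one kernel; conjugate = TRUE gives the adjoint operator (used for
# reverse-mode gradients). ufft, if given, is the cached fft of the padded u.
rs_apply <- function(u, prep, kernel = "z", conjugate = FALSE, ufft = NULL) {
  if (is.null(ufft)) ufft <- stats::fft(rs_pad(u, prep))
  H <- prep$H[[kernel]]
  if (conjugate) H <- Conj(H)
  rs_crop(fft2(ufft * H, inverse = TRUE), prep)
}

rs_check_sampling <- function(grid, wavelength, z) {
  if (z == 0) return(invisible())
  width <- max(grid$nx * grid$pitch[1], grid$ny * grid$pitch[2])
  if (max(grid$pitch) > wavelength_um(wavelength) * abs(z) / width)
    warning("RS sampling criterion violated (pitch > lambda*z/width); ",
            "results may alias for this short hop", call. = FALSE)
  invisible()
}

rs_check_containment <- function(u, grid) {
  ptot <- sum(Mod(u)^2)
  if (ptot == 0) return(invisible())
  fx <- max(1L, round(0.1 * grid$nx)); fy <- max(1L, round(0.1 * grid$ny))
  inner <- u[(fy + 1):(grid$ny - fy), (fx + 1):(grid$nx - fx)]
  frac <- 1 - sum(Mod(inner)^2) / ptot
  if (frac > 0.01)
    warning(sprintf(
      "field is poorly contained: %.2g%% of its power lies in the outer 10%% frame",
      100 * frac), call. = FALSE)
  invisible()
}

#' Rayleigh-Sommerfeld free-space propagation
#'
#' Propagates a scalar field a distance `z` (micrometres) between parallel
#' planes using the exact first Rayleigh-Sommerfeld diffraction integral,
#' evaluated as an FFT convolution with the spherical-wave kernel on a grid
#' zero-padded to twice the linear size. Negative `z` back-propagates with the
#' conjugate kernel (evanescent waves are attenuated, never amplified).
#'
#' A warning (not an error) is raised when the kernel is undersampled
#' (`pitch > lambda*z/width`) or when more than 1% of the input power sits in
#' the outer 10% frame of the grid, since wrap-around then pollutes the
#' result.
#'
#' @param field An `ol_scalar_field`.
#' @param z Propagation distance in micrometres (may be negative).
#' @return An `ol_scalar_field` on the same grid.
#' @export
propagate_rs <- function(field, z) {
  stopifnot(inherits(field, "ol_scalar_field"))
  if (!is.finite(z)) stop("'z' must be finite")
  if (z == 0) return(field)
  rs_check_sampling(field$grid, field$wavelength, z)
  rs_check_containment(field$u, field$grid)
  prep <- rs_prep(field$grid, field$wavelength, z, "z")
  scalar_field(field$grid, rs_apply(field$u, prep, "z"), field$wavelength)
}

#' Output window for zoomed (chirped z-transform) propagation
#'
#' Describes the detector-plane raster on which a zoom propagation is
#' evaluated: it need not match the input grid in either extent or pixel
#' count, which is the point of the chirped z-transform.
#'
#' @param nx,ny Output pixel counts.
#' @param extent_x,extent_y Physical half-widths of the window (micrometres).
#' @param center Window center `c(x, y)` in micrometres.
#' @return An `ol_output_window` object.
#' @export
output_window <- function(nx, ny, extent_x, extent_y = extent_x, center = c(0, 0)) {
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (nx < 2L || ny < 2L) stop("output window needs at least 2 x 2 pixels")
  if (!all(is.finite(c(extent_x, extent_y))) || extent_x <= 0 || extent_y <= 0)
    stop("window extents must be positive")
  structure(list(nx = nx, ny = ny, extent_x = extent_x, extent_y = extent_y,
                 center = as.numeric(center)),
            class = "ol_output_window")
}

window_grid <- function(window) {
  make_grid(window$nx, window$ny,
            c(2 * window$extent_x / window$nx, 2 * window$extent_y / window$ny))
}

# window congruent with a grid (same raster, centered)
window_from_grid <- function(grid) {
  output_window(grid$nx, grid$ny,
                grid$nx * grid$pitch[1] / 2, grid$ny * grid$pitch[2] / 2)
}

# Evaluate the inverse transform of the padded spectrum V (fft order) on the
# window raster via Bluestein. Returns the complex raster on the window grid.
czt_evaluate <- function(V, prep, window) {
  grid <- prep$grid
  ogrid <- window_grid(window)
  # offset between the field's centered coordinates and the padded FFT
  # lattice (whose natural coordinate is index * pitch, zero-based)
  shift_x <- (prep$ox + (grid$nx - 1) / 2) * grid$pitch[1]
  shift_y <- (prep$oy + (grid$ny - 1) / 2) * grid$pitch[2]
  xo <- ogrid$x + window$center[1] + shift_x
  yo <- ogrid$y + window$center[2] + shift_y
  kx <- 2 * pi / (prep$px * grid$pitch[1]) * (seq_len(prep$px) - 1 - floor(prep$px / 2))
  ky <- 2 * pi / (prep$py * grid$pitch[2]) * (seq_len(prep$py) - 1 - floor(prep$py / 2))
  Vs <- fftshift2(V)
  out <- zoom_dft2(Vs,
                   x0 = kx[1], dx = kx[2] - kx[1],
                   y0 = ky[1], dy = ky[2] - ky[1],
                   kx0 = xo[1], dkx = xo[2] - xo[1], mx = window$nx,
                   ky0 = yo[1], dky = yo[2] - yo[1], my = window$ny,
                   sgn = 1)
  out / (prep$px * prep$py)
}

# adjoint of czt_evaluate as a linear map from V to the window raster
czt_evaluate_adjoint <- function(gwin, prep, window) {
  grid <- prep$grid
  ogrid <- window_grid(window)
  shift_x <- (prep$ox + (grid$nx - 1) / 2) * grid$pitch[1]
  shift_y <- (prep$oy + (grid$ny - 1) / 2) * grid$pitch[2]
  xo <- ogrid$x + window$center[1] + shift_x
  yo <- ogrid$y + window$center[2] + shift_y
  kx <- 2 * pi / (prep$px * grid$pitch[1]) * (seq_len(prep$px) - 1 - floor(prep$px / 2))
  ky <- 2 * pi / (prep$py * grid$pitch[2]) * (seq_len(prep$py) - 1 - floor(prep$py / 2))
  Vs_grad <- zoom_dft2(gwin,
                       x0 = xo[1], dx = xo[2] - xo[1],
                       y0 = yo[1], dy = yo[2] - yo[1],
                       kx0 = kx[1], dkx = kx[2] - kx[1], mx = prep$px,
                       ky0 = ky[1], dky = ky[2] - ky[1], my = prep$py,
                       sgn = -1)
  ifftshift2(Vs_grad) / (prep$px * prep$py)
}

#' Zoomed Rayleigh-Sommerfeld propagation via the chirped z-transform
#'
#' Evaluates the same diffraction integral as [propagate_rs()] but samples the
#' output on an arbitrary window (position, extent and pixel count free),
#' using Bluestein's chirped z-transform for the final inverse transform. On a
#' window congruent with the input grid it reproduces [propagate_rs()] to
#' floating-point accuracy.
#'
#' @param field An `ol_scalar_field`.
#' @param z Propagation distance in micrometres.
#' @param window An [output_window()].
#' @return An `ol_scalar_field` on the window raster (coordinates relative to
#'   the window center).
#' @export
propagate_czt <- function(field, z, window) {
  stopifnot(inherits(field, "ol_scalar_field"), inherits(window, "ol_output_window"))
  if (!is.finite(z)) stop("'z' must be finite")
  rs_check_sampling(field$grid, field$wavelength, z)
  prep <- rs_prep(field$grid, field$wavelength, z, "z")
  V <- stats::fft(rs_pad(field$u, prep))
  if (z != 0) V <- V * prep$H[["z"]]
  scalar_field(window_grid(window), czt_evaluate(V, prep, window), field$wavelength)
}

vrs_check_input <- function(field) {
  stopifnot(inherits(field, "ol_vector_field"))
  scale <- max(Mod(field$ex), Mod(field$ey), 1e-300)
  if (max(Mod(field$ez)) > 1e-9 * scale)
    stop("vectorial propagation expects a transverse input (ez = 0 at the source plane)")
}

#' Vectorial Rayleigh-Sommerfeld propagation
#'
#' Propagates the transverse components with the scalar RS kernel and
#' synthesizes the longitudinal component from the x- and y-weighted kernel
#' derivatives of the spherical wave, so that the output spectrum satisfies
#' the divergence-free (Maxwell) condition. The input must be transverse
#' (`ez = 0`), the source-plane convention.
#'
#' @param field An `ol_vector_field` with `ez = 0`.
#' @param z Propagation distance in micrometres.
#' @return An `ol_vector_field` (all three components) on the same grid.
#' @export
propagate_vrs <- function(field, z) {
  vrs_check_input(field)
  if (!is.finite(z)) stop("'z' must be finite")
  if (z == 0) return(field)
  rs_check_sampling(field$grid, field$wavelength, z)
  rs_check_containment(field$ex, field$grid)
  prep <- rs_prep(field$grid, field$wavelength, z, c("z", "x", "y"))
  fx <- stats::fft(rs_pad(field$ex, prep))
  fy <- stats::fft(rs_pad(field$ey, prep))
  ex <- rs_crop(fft2(fx * prep$H[["z"]], inverse = TRUE), prep)
  ey <- rs_crop(fft2(fy * prep$H[["z"]], inverse = TRUE), prep)
  ez <- rs_crop(fft2(fx * prep$H[["x"]] + fy * prep$H[["y"]], inverse = TRUE), prep)
  vector_field(field$grid, ex, ey, ez, wavelength = field$wavelength)
}

#' Zoomed vectorial Rayleigh-Sommerfeld propagation
#'
#' Vectorial counterpart of [propagate_czt()]: the three output components of
#' [propagate_vrs()] evaluated on an arbitrary output window.
#'
#' @inheritParams propagate_vrs
#' @param window An [output_window()].
#' @return An `ol_vector_field` on the window raster.
#' @export
propagate_vczt <- function(field, z, window) {
  vrs_check_input(field)
  stopifnot(inherits(window, "ol_output_window"))
  if (!is.finite(z)) stop("'z' must be finite")
  rs_check_sampling(field$grid, field$wavelength, z)
  prep <- rs_prep(field$grid, field$wavelength, z, c("z", "x", "y"))
  fx <- stats::fft(rs_pad(field$ex, prep))
  fy <- stats::fft(rs_pad(field$ey, prep))
  og <- window_grid(window)
  if (z == 0) {
    ex <- czt_evaluate(fx, prep, window)
    ey <- czt_evaluate(fy, prep, window)
    return(vector_field(og, ex, ey, wavelength = field$wavelength))
  }
  ex <- czt_evaluate(fx * prep$H[["z"]], prep, window)
  ey <- czt_evaluate(fy * prep$H[["z"]], prep, window)
  ez <- czt_evaluate(fx * prep$H[["x"]] + fy * prep$H[["y"]], prep, window)
  vector_field(og, ex, ey, ez, wavelength = field$wavelength)
}

# ---- Richards-Wolf high-NA focusing -----------------------------------------

# Precompute the aplanatic-lens geometry: direction cosines, apodization and
# the meridional polarization rotation for every pupil pixel.
focus_prep <- function(grid, wavelength, na, focal, n_medium = 1.0) {
  if (!is.finite(na) || na <= 0 || na >= n_medium)
    stop("need 0 < na < refractive index of the medium")
  if (!is.finite(focal) || focal <= 0) stop("'focal' must be positive (micrometres)")
  k <- wavenumber(wavelength) * n_medium
  X <- grid_xmat(grid); Y <- grid_ymat(grid)
  rho <- sqrt(X^2 + Y^2)
  sin_t <- rho / focal                    # aplanatic mapping rho = f sin(theta)
  aperture <- sin_t <= (na / n_medium)
  sin_t[!aperture] <- 0
  cos_t <- sqrt(pmax(0, 1 - sin_t^2))
  phi <- atan2(Y, X)
  list(k = k, X = X, Y = Y, aperture = aperture,
       sin_t = sin_t, cos_t = cos_t,
       cos_p = cos(phi), sin_p = sin(phi),
       apod = sqrt(cos_t) * aperture,
       focal = focal, grid = grid)
}

# strength vectors on the exit sphere for given transverse pupil field
focus_strength <- function(ex, ey, fp) {
  e_rho <- ex * fp$cos_p + ey * fp$sin_p
  e_phi <- -ex * fp$sin_p + ey * fp$cos_p
  w <- fp$apod / pmax(fp$cos_t, 1e-12)   # apodization and 1/sz Debye weight
  list(
    ax = w * (e_rho * fp$cos_t * fp$cos_p - e_phi * fp$sin_p),
    ay = w * (e_rho * fp$cos_t * fp$sin_p + e_phi * fp$cos_p),
    az = w * (e_rho * fp$sin_t)
  )
}

# zoom transform from direction cosines to the focal window; linear in `a`
focus_transform <- function(a, fp, window) {
  grid <- fp$grid
  og <- window_grid(window)
  sx <- grid$x / fp$focal
  sy <- grid$y / fp$focal
  xo <- og$x + window$center[1]
  yo <- og$y + window$center[2]
  pref <- -1i * fp$k * fp$focal / (2 * pi) * (grid$pitch[1] / fp$focal) *
    (grid$pitch[2] / fp$focal)
  pref * zoom_dft2(a,
                   x0 = sx[1], dx = sx[2] - sx[1],
                   y0 = sy[1], dy = sy[2] - sy[1],
                   kx0 = fp$k * xo[1], dkx = fp$k * (xo[2] - xo[1]), mx = window$nx,
                   ky0 = fp$k * yo[1], dky = fp$k * (yo[2] - yo[1]), my = window$ny,
                   sgn = 1)
}

focus_transform_adjoint <- function(gwin, fp, window) {
  grid <- fp$grid
  og <- window_grid(window)
  sx <- grid$x / fp$focal
  sy <- grid$y / fp$focal
  xo <- og$x + window$center[1]
  yo <- og$y + window$center[2]
  pref <- -1i * fp$k * fp$focal / (2 * pi) * (grid$pitch[1] / fp$focal) *
    (grid$pitch[2] / fp$focal)
  Conj(pref) * zoom_dft2(gwin,
                         x0 = fp$k * xo[1], dx = fp$k * (xo[2] - xo[1]),
                         y0 = fp$k * yo[1], dy = fp$k * (yo[2] - yo[1]),
                         kx0 = sx[1], dkx = sx[2] - sx[1], mx = grid$nx,
                         ky0 = sy[1], dky = sy[2] - sy[1], my = grid$ny,
                         sgn = -1)
}

#' Richards-Wolf high-NA vectorial focusing
#'
#' Focuses the transverse pupil field of an aplanatic objective onto its
#' focal plane using the Richards-Wolf (Debye-Wolf) vector diffraction
#' integral: `sqrt(cos(theta))` apodization, rotation of the polarization
#' into the meridional frame, and evaluation of the angular spectrum sum on
#' the focal window via the chirped z-transform. The returned field contains
#' all three Cartesian components, including the longitudinal `ez` that
#' dominates the tight focus of radially polarized light.
#'
#' The pupil raster maps to the exit sphere through the aplanatic relation
#' `rho = focal * sin(theta)`; pupil pixels with `sin(theta) > na / n_medium`
#' fall outside the aperture stop and are discarded.
#'
#' @param field An `ol_vector_field` on the pupil plane (`ez` ignored; must be
#'   transverse).
#' @param na Numerical aperture, `0 < na < n_medium`.
#' @param focal Focal length in micrometres.
#' @param window An [output_window()] describing the focal-plane raster.
#' @param n_medium Refractive index of the immersion medium (default 1, air).
#' @return An `ol_vector_field` on the focal window.
#' @export
focus_high_na <- function(field, na, focal, window, n_medium = 1.0) {
  stopifnot(inherits(field, "ol_vector_field"), inherits(window, "ol_output_window"))
  fp <- focus_prep(field$grid, field$wavelength, na, focal, n_medium)
  a <- focus_strength(field$ex, field$ey, fp)
  og <- window_grid(window)
  vector_field(og,
               ex = focus_transform(a$ax, fp, window),
               ey = focus_transform(a$ay, fp, window),
               ez = focus_transform(a$az, fp, window),
               wavelength = field$wavelength)
}
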