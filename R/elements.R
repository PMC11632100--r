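# Parametric optical elements with experimental imperfection models:
# phase masks / SLMs, the polarization-resolved super-SLM, wave plates,
# tunable beam splitters and the radial polarization converter.

#' Experimental imperfection model for optical elements
#'
#' Describes the imperfections applied when an element acts on a field:
#' per-pixel uniform phase noise on SLMs (scalar on wave plates), uniform
#' transverse misalignment of masks, multiplicative perturbation of beam
#' splitter ratios, and optional quantization of mask phases to `2^bits`
#' uniform levels (real SLM drivers are typically 8-bit). All draws are
#' reproducible given `seed`.
#'
#' The "standard experimental conditions" envelope uses half-ranges of
#' 0.05 rad phase noise, 0.05 mm misalignment and 1% beam-splitter
#' imperfection (midpoints of the +-(0.01-0.1) device-quality band); the
#' stress envelope uses 0.55 rad / 0.55 mm (midpoints of +-(0.1-1)).
#'
#' @param phase_noise Half-range of uniform phase noise, radians.
#' @param misalign Half-range of uniform transverse misalignment,
#'   millimetres (each axis drawn independently).
#' @param bs_imperfection Relative perturbation of beam-splitter T/R
#'   (fraction, e.g. 0.01 for 1%).
#' @param seed Integer seed making every draw reproducible.
#' @param quantize_bits If non-`NULL`, mask phases are discretized to
#'   `2^quantize_bits` uniform levels over (-pi, pi] before application.
#' @param perturb_theta Should wave-plate noise also enter the orientation
#'   angle theta? Default `FALSE`: noise perturbs the retardance eta only.
#' @return An `ol_noise_model` object.
#' @export
noise_model <- function(phase_noise = 0, misalign = 0, bs_imperfection = 0,
                        seed = 1L, quantize_bits = NULL, perturb_theta = FALSE) {
  stopifnot(phase_noise >= 0, misalign >= 0, bs_imperfection >= 0)
  structure(list(phase_noise = phase_noise, misalign = misalign,
                 bs_imperfection = bs_imperfection, seed = as.integer(seed),
                 quantize_bits = quantize_bits, perturb_theta = perturb_theta),
            class = "ol_noise_model")
}

#' @rdname noise_model
#' @export
noise_standard <- function(seed = 1L) noise_model(0.05, 0.05, 0.01, seed = seed)

#' @rdname noise_model
#' @param eight_bit Quantize SLM phases to 8 bits in the stress model.
#' @export
noise_stress <- function(seed = 1L, eight_bit = FALSE)
  noise_model(0.55, 0.55, 0.01, seed = seed,
              quantize_bits = if (eight_bit) 8L else NULL)

noise_is_null <- function(noise) {
  is.null(noise) ||
    (noise$phase_noise == 0 && noise$misalign == 0 &&
       noise$bs_imperfection == 0 && is.null(noise$quantize_bits))
}

# draw `n` uniforms in [-1, 1] from the model's private stream; `salt`
# decorrelates different elements sharing one model without touching the
# global RNG state
noise_draw <- function(noise, n, salt = 0L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((noise$seed + 1000003L * as.integer(salt)) %% .Machine$integer.max)
  stats::runif(n, -1, 1)
}

#' Phase mask on a grid
#'
#' A raster of phases in radians, wrapped to (-pi, pi], tied to a grid.
#'
#' @param values Numeric matrix of phases (ny x nx).
#' @param grid The `ol_grid` it lives on.
#' @return An `ol_phase_mask`.
#' @export
phase_mask <- function(values, grid) {
  stopifnot(inherits(grid, "ol_grid"))
  if (is.null(dim(values)) || nrow(values) != grid$ny || ncol(values) != grid$nx)
    stop("mask shape must match the grid")
  if (any(!is.finite(values))) stop("mask values must be finite")
  structure(list(values = wrap_phase(values), grid = grid), class = "ol_phase_mask")
}

#' Canonical masks: spiral (vortex) and quadratic lens phases
#'
#' `spiral_mask()` builds the azimuthal phase `charge * atan2(y, x)` whose
#' focus carries an on-axis null (the doughnut used as a depletion beam);
#' `lens_mask()` builds the thin-lens quadratic phase
#' `-k (x^2 + y^2) / (2 focal)`.
#'
#' @param grid An `ol_grid`.
#' @param charge Integer topological charge (0 gives a zero mask).
#' @return An `ol_phase_mask`.
#' @export
spiral_mask <- function(grid, charge = 1L) {
  phi <- atan2(grid_ymat(grid), grid_xmat(grid))
  phase_mask(charge * phi, grid)
}

#' @rdname spiral_mask
#' @param focal Focal length in micrometres (`Inf` gives a zero mask).
#' @param wavelength Vacuum wavelength in nanometres.
#' @export
lens_mask <- function(grid, focal, wavelength) {
  check_wavelength(wavelength)
  if (!is.finite(focal)) return(phase_mask(matrix(0, grid$ny, grid$nx), grid))
  if (focal == 0) stop("'focal' must be nonzero")
  k <- wavenumber(wavelength)
  r2 <- grid_xmat(grid)^2 + grid_ymat(grid)^2
  phase_mask(-k * r2 / (2 * focal), grid)
}

# effective complex transmission of a mask under a noise model: quantization,
# band-limited misalignment shift, per-pixel phase noise
mask_transmission <- function(mask, grid, noise, salt = 0L) {
  vals <- if (inherits(mask, "ol_phase_mask")) mask$values else mask
  if (!is.null(noise) && !is.null(noise$quantize_bits)) {
    lv <- 2^noise$quantize_bits
    vals <- wrap_phase(round((vals + pi) / (2 * pi) * lv) / lv * 2 * pi - pi)
  }
  tr <- exp(1i * vals)
  if (!is.null(noise) && noise$misalign > 0) {
    d <- noise_draw(noise, 2, salt = salt) * noise$misalign * 1000  # mm -> um
    tr <- shift_raster(tr, grid, d[1], d[2])
  }
  if (!is.null(noise) && noise$phase_noise > 0) {
    u <- matrix(noise_draw(noise, grid$ny * grid$nx, salt = salt + 1L),
                grid$ny, grid$nx) * noise$phase_noise
    tr <- tr * exp(1i * u)
  }
  tr
}

# band-limited subpixel translation via a Fourier phase ramp
shift_raster <- function(m, grid, dx_um, dy_um) {
  ny <- nrow(m); nx <- ncol(m)
  kx <- 2 * pi / (nx * grid$pitch[1]) * c(0:(nx %/% 2 - 1), -(nx - nx %/% 2):-1)
  ky <- 2 * pi / (ny * grid$pitch[2]) * c(0:(ny %/% 2 - 1), -(ny - ny %/% 2):-1)
  ramp <- exp(-1i * (outer(ky * dy_um, kx * 0, `+`) + outer(ky * 0, kx * dx_um, `+`)))
  fft2(fft2(m) * ramp, inverse = TRUE)
}

#' Spatial light modulator: programmable phase raster
#'
#' Multiplies the selected polarization component(s) by `exp(1i * mask)`,
#' after applying the noise model: optional 8-bit quantization of the mask,
#' band-limited translation by the sampled misalignment, and per-pixel
#' uniform phase noise. A pure phase element: total power is conserved
#' exactly when no misalignment resampling is involved.
#'
#' @param field An `ol_vector_field`.
#' @param mask An `ol_phase_mask` on the same grid.
#' @param component Which polarization the panel addresses: `"H"` (x), `"V"`
#'   (y) or `"both"`.
#' @param noise An [noise_model()] or `NULL` for the ideal element.
#' @return The modulated `ol_vector_field`.
#' @export
apply_slm <- function(field, mask, component = c("both", "H", "V"), noise = NULL) {
  component <- match.arg(component)
  stopifnot(inherits(field, "ol_vector_field"), inherits(mask, "ol_phase_mask"))
  stop_if_grid_mismatch(field$grid, mask$grid, "field and mask")
  tr <- mask_transmission(mask, field$grid, noise)
  ex <- field$ex; ey <- field$ey
  if (component %in% c("both", "H")) ex <- ex * tr
  if (component %in% c("both", "V")) ey <- ey * tr
  vector_field(field$grid, ex, ey, field$ez, wavelength = field$wavelength)
}

#' Super-SLM: independent phase rasters on each polarization
#'
#' Two stacked SLM panels addressing the horizontal and vertical components
#' independently (counts as 2 SLM panels in element audits). Noise draws for
#' the two panels are independent.
#'
#' @inheritParams apply_slm
#' @param mask_h,mask_v `ol_phase_mask` objects for the H and V panels.
#' @return The modulated `ol_vector_field`.
#' @export
super_slm <- function(field, mask_h, mask_v, noise = NULL) {
  stopifnot(inherits(field, "ol_vector_field"))
  stop_if_grid_mismatch(field$grid, mask_h$grid, "field and H mask")
  stop_if_grid_mismatch(field$grid, mask_v$grid, "field and V mask")
  th <- mask_transmission(mask_h, field$grid, noise, salt = 0L)
  tv <- mask_transmission(mask_v, field$grid, noise, salt = 11L)
  vector_field(field$grid, field$ex * th, field$ey * tv, field$ez,
               wavelength = field$wavelength)
}

#' Wave plate parameters
#'
#' @param eta Phase retardance in radians (pi: half-wave, pi/2: quarter-wave).
#' @param theta Fast-axis orientation in radians.
#' @return An `ol_wave_plate` parameter object.
#' @export
wave_plate_params <- function(eta, theta) {
  stopifnot(is.finite(eta), is.finite(theta))
  structure(list(eta = eta, theta = theta), class = "ol_wave_plate")
}

# Jones matrix of a retarder: R(theta) diag(exp(-i eta/2), exp(+i eta/2)) R(-theta)
wave_plate_jones <- function(eta, theta) {
  ct <- cos(theta); st <- sin(theta)
  em <- exp(-1i * eta / 2); ep <- exp(1i * eta / 2)
  matrix(c(ct^2 * em + st^2 * ep, ct * st * (em - ep),
           ct * st * (em - ep),   st^2 * em + ct^2 * ep),
         2, 2)
}

# and its analytic parameter derivatives (used by the adjoint engine)
wave_plate_jones_deta <- function(eta, theta) {
  ct <- cos(theta); st <- sin(theta)
  em <- -1i / 2 * exp(-1i * eta / 2); ep <- 1i / 2 * exp(1i * eta / 2)
  matrix(c(ct^2 * em + st^2 * ep, ct * st * (em - ep),
           ct * st * (em - ep),   st^2 * em + ct^2 * ep),
         2, 2)
}

wave_plate_jones_dtheta <- function(eta, theta) {
  ct <- cos(theta); st <- sin(theta)
  em <- exp(-1i * eta / 2); ep <- exp(1i * eta / 2)
  d <- em - ep
  matrix(c(-2 * ct * st * em + 2 * st * ct * ep, (ct^2 - st^2) * d,
           (ct^2 - st^2) * d,                    -2 * st * ct * em + 2 * ct * st * ep),
         2, 2)
}

#' Wave plate (variable retarder)
#'
#' Applies the Jones transform
#' `J = R(theta) diag(exp(-i eta/2), exp(+i eta/2)) R(-theta)` pixel-wise to
#' the transverse components. Phase noise perturbs the retardance `eta`
#' (and, if the noise model says so, `theta`) by one scalar uniform draw.
#'
#' @param field An `ol_vector_field`.
#' @param wp An [wave_plate_params()] object.
#' @param noise An [noise_model()] or `NULL`.
#' @return The transformed `ol_vector_field`.
#' @export
wave_plate <- function(field, wp, noise = NULL) {
  stopifnot(inherits(field, "ol_vector_field"), inherits(wp, "ol_wave_plate"))
  eta <- wp$eta; theta <- wp$theta
  if (!is.null(noise) && noise$phase_noise > 0) {
    d <- noise_draw(noise, 2, salt = 23L) * noise$phase_noise
    eta <- eta + d[1]
    if (isTRUE(noise$perturb_theta)) theta <- theta + d[2]
  }
  J <- wave_plate_jones(eta, theta)
  vector_field(field$grid,
               ex = J[1, 1] * field$ex + J[1, 2] * field$ey,
               ey = J[2, 1] * field$ex + J[2, 2] * field$ey,
               ez = field$ez,
               wavelength = field$wavelength)
}

#' Tunable beam splitter parameters
#'
#' @param t,r Transmittance and reflectance, both in `[0, 1]`. In lossless
#'   mode (the default throughout the package) `t + r` must equal 1.
#' @param lossless Enforce `t + r = 1`.
#' @return An `ol_beam_splitter` parameter object.
#' @export
beam_splitter_params <- function(t, r = 1 - t, lossless = TRUE) {
  stopifnot(is.finite(t), is.finite(r), t >= 0, t <= 1, r >= 0, r <= 1)
  if (t + r > 1 + 1e-12) stop("beam splitter must be passive: T + R <= 1")
  if (lossless && abs(t + r - 1) > 1e-9)
    stop("lossless beam splitter requires T + R = 1")
  structure(list(t = t, r = r, lossless = lossless), class = "ol_beam_splitter")
}

#' Tunable (non-polarizing) beam splitter
#'
#' Mixes two input fields with the symmetric lossless 2x2 scattering matrix
#' `out_c = sqrt(T) a + 1i sqrt(R) b`, `out_d = 1i sqrt(R) a + sqrt(T) b`
#' (the `1i`-on-reflection phase convention), applied per component and
#' pixel. Either input may be `NULL`, meaning a dark port. Under a noise
#' model, the effective `(T, R)` are perturbed multiplicatively by up to
#' `bs_imperfection` and renormalized to lossless.
#'
#' With `polarizing = TRUE` the element acts as an ideal polarizing splitter
#' instead: horizontal components transmit, vertical components reflect
#' (with the same `1i` reflection phase), and the `(T, R)` ratios are
#' ignored.
#'
#' @param in_a,in_b `ol_vector_field`s on equal grids (or `NULL` for a dark
#'   port; at least one must be a field).
#' @param bs An [beam_splitter_params()] object.
#' @param noise An [noise_model()] or `NULL`.
#' @param polarizing Use the polarizing variant.
#' @return A list with fields `c` and `d`, the two output ports.
#' @export
beam_splitter <- function(in_a, in_b, bs, noise = NULL, polarizing = FALSE) {
  stopifnot(inherits(bs, "ol_beam_splitter"))
  if (is.null(in_a) && is.null(in_b)) stop("at least one input port must carry a field")
  if (is.null(in_a)) in_a <- zero_field_like(in_b)
  if (is.null(in_b)) in_b <- zero_field_like(in_a)
  stop_if_grid_mismatch(in_a$grid, in_b$grid, "beam splitter inputs")
  if (polarizing) {
    out_c <- vector_field(in_a$grid, in_a$ex, 1i * in_b$ey,
                          wavelength = in_a$wavelength)
    out_d <- vector_field(in_a$grid, in_b$ex, 1i * in_a$ey,
                          wavelength = in_a$wavelength)
    return(list(c = out_c, d = out_d))
  }
  tr <- effective_bs_ratios(bs, noise)
  ct <- sqrt(tr$t); cr <- 1i * sqrt(tr$r)
  out_c <- vector_field(in_a$grid,
                        ct * in_a$ex + cr * in_b$ex,
                        ct * in_a$ey + cr * in_b$ey,
                        ct * in_a$ez + cr * in_b$ez,
                        wavelength = in_a$wavelength)
  out_d <- vector_field(in_a$grid,
                        cr * in_a$ex + ct * in_b$ex,
                        cr * in_a$ey + ct * in_b$ey,
                        cr * in_a$ez + ct * in_b$ez,
                        wavelength = in_a$wavelength)
  list(c = out_c, d = out_d)
}

effective_bs_ratios <- function(bs, noise = NULL) {
  t <- bs$t; r <- bs$r
  if (!is.null(noise) && noise$bs_imperfection > 0) {
    d <- noise_draw(noise, 2, salt = 37L) * noise$bs_imperfection
    t <- t * (1 + d[1]); r <- r * (1 + d[2])
    s <- t + r
    if (s > 0) { t <- t / s; r <- r / s }  # renormalize to lossless
  }
  list(t = max(0, min(1, t)), r = max(0, min(1, r)))
}

zero_field_like <- function(f) {
  z <- matrix(0 + 0i, f$grid$ny, f$grid$nx)
  vector_field(f$grid, z, z, z, wavelength = f$wavelength)
}

#' Radial polarization converter
#'
#' Rotates the polarization of a linearly polarized beam to the local radial
#' direction at every pixel, using the azimuthally varying half-wave-plate
#' model of the classic segmented converter: at azimuth `phi` the fast axis
#' sits at `(phi + alpha)/2`, where `alpha` is the input polarization angle,
#' so a linear input emerges radially polarized with its amplitude and
#' wavefront preserved pixel-wise. The map is linear in the field, which
#' keeps it differentiable inside optimized setups. The on-axis pixel, where
#' the radial direction is undefined, is zeroed by convention.
#'
#' @param field A linearly polarized `ol_vector_field`.
#' @return An `ol_vector_field` with `(ex, ey) = |E| (cos(phi), sin(phi))`
#'   times the input wavefront phase.
#' @export
radial_converter <- function(field) {
  stopifnot(inherits(field, "ol_vector_field"))
  check_linear_polarization(field)
  alpha <- input_polarization_angle(field)
  M <- radial_converter_matrices(field$grid, alpha)
  vector_field(field$grid,
               M$mxx * field$ex + M$mxy * field$ey,
               M$myx * field$ex + M$myy * field$ey,
               wavelength = field$wavelength)
}

# global polarization angle of a (near-)linear field
input_polarization_angle <- function(field) {
  px <- sum(Mod(field$ex)^2); py <- sum(Mod(field$ey)^2)
  if (px == 0 && py == 0) return(0)
  # signed amplitudes via projection on the dominant component's phase
  ref <- if (px >= py) field$ex else field$ey
  i0 <- which.max(Mod(ref))
  ph <- Arg(ref[i0])
  ax <- sum(Re(field$ex * exp(-1i * ph))); ay <- sum(Re(field$ey * exp(-1i * ph)))
  atan2(ay, ax)
}

# pointwise Jones matrices of the azimuthal half-wave plate (fast axis at
# (phi + alpha)/2); the singular on-axis pixel is zeroed
radial_converter_matrices <- function(grid, alpha = 0) {
  X <- grid_xmat(grid); Y <- grid_ymat(grid)
  phi <- atan2(Y, X)
  a <- phi + alpha
  sing <- sqrt(X^2 + Y^2) < min(grid$pitch) / 2
  cs <- cos(a); sn <- sin(a)
  cs[sing] <- 0; sn[sing] <- 0
  list(mxx = cs, mxy = sn, myx = sn, myy = -cs)
}

check_linear_polarization <- function(field, tol = 1e-6) {
  px <- sum(Mod(field$ex)^2); py <- sum(Mod(field$ey)^2)
  if (px > tol * py && py > tol * px) {
    # both components significant: relative phase must be 0 or pi everywhere
    m <- Mod(field$ex) > 0 & Mod(field$ey) > 0
    dphi <- wrap_phase(Arg(field$ex[m]) - Arg(field$ey[m]))
    if (any(pmin(abs(dphi), abs(abs(dphi) - pi)) > 1e-6))
      stop("radial converter expects a linearly polarized input")
  }
  invisible()
}
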