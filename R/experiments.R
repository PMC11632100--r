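# Fixture generation (amplitude masks, training pairs), the ideal 4f relay
# reference, magnification estimation, and the robustness protocol.

#' Generate a binary amplitude mask
#'
#' Deterministic test patterns used as imaging inputs: a solid isosceles
#' `triangle` centered on the axis, a seeded multi-component `blob_logo`
#' silhouette (a synthetic stand-in for a complex logo-like structure),
#' seeded `random_shapes` (rectangles and disks), and a single-pixel
#' `delta`.
#'
#' @param grid An `ol_grid`.
#' @param kind One of `"triangle"`, `"blob_logo"`, `"random_shapes"`,
#'   `"delta"`.
#' @param size_fraction Linear size of the pattern relative to the grid
#'   width, in (0, 1).
#' @param seed Seed for the random kinds; equal seeds give bit-identical
#'   masks.
#' @param spread Half-range of random shape centers as a fraction of the
#'   grid width.
#' @return A numeric matrix in `[0, 1]` on the grid.
#' @export
make_mask <- function(grid, kind = c("triangle", "blob_logo", "random_shapes", "delta"),
                      size_fraction = 0.3, seed = 1L, spread = 0.25) {
  kind <- match.arg(kind)
  stopifnot(size_fraction > 0, size_fraction < 1)
  X <- grid_xmat(grid); Y <- grid_ymat(grid)
  W <- grid$nx * grid$pitch[1]; H <- grid$ny * grid$pitch[2]
  if (kind == "delta") {
    m <- matrix(0, grid$ny, grid$nx)
    m[which.min(abs(grid$y)), which.min(abs(grid$x))] <- 1
    return(m)
  }
  if (kind == "triangle") {
    b <- size_fraction * W; h <- size_fraction * H
    # apex up at (0, h/2), base corners (+-b/2, -h/2)
    inside <- (Y >= -h / 2) &
      (Y - h / 2 <= (-h / b * 2) * X) &
      (Y - h / 2 <= (h / b * 2) * X)
    return(matrix(as.numeric(inside), grid$ny, grid$nx))
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  m <- matrix(0, grid$ny, grid$nx)
  n_shapes <- if (kind == "blob_logo") 7L else sample(3:6, 1)
  for (i in seq_len(n_shapes)) {
    cx <- stats::runif(1, -spread, spread) * W
    cy <- stats::runif(1, -spread, spread) * H
    s <- stats::runif(1, 0.25, 0.8) * size_fraction
    if (kind == "blob_logo" || stats::runif(1) < 0.5) {
      rx <- s * W / 2 * stats::runif(1, 0.4, 1)
      ry <- s * H / 2 * stats::runif(1, 0.4, 1)
      m[((X - cx) / rx)^2 + ((Y - cy) / ry)^2 <= 1] <- 1
    } else {
      hw <- s * W / 2; hh <- s * H / 2 * stats::runif(1, 0.4, 1)
      m[abs(X - cx) <= hw & abs(Y - cy) <= hh] <- 1
    }
  }
  m
}

# bilinear sampling of img at physical coordinates (xs, ys); zero outside
bilinear_sample <- function(img, grid, XS, YS) {
  fx <- (XS - grid$x[1]) / grid$pitch[1]
  fy <- (YS - grid$y[1]) / grid$pitch[2]
  i0 <- floor(fy); j0 <- floor(fx)
  ty <- fy - i0; tx <- fx - j0
  at <- function(ii, jj) {
    ok <- ii >= 0 & ii <= grid$ny - 1 & jj >= 0 & jj <= grid$nx - 1
    v <- numeric(length(ii))
    v[ok] <- img[cbind(ii[ok] + 1L, jj[ok] + 1L)]
    v
  }
  v <- (1 - tx) * (1 - ty) * at(i0, j0) + tx * (1 - ty) * at(i0, j0 + 1) +
    (1 - tx) * ty * at(i0 + 1, j0) + tx * ty * at(i0 + 1, j0 + 1)
  matrix(v, grid$ny, grid$nx)
}

# the ideal imaging map of a 4f relay: point reflection through the axis and
# scaling by the magnification
imaging_map <- function(img, grid, magnification) {
  X <- grid_xmat(grid); Y <- grid_ymat(grid)
  bilinear_sample(img, grid, -X / magnification, -Y / magnification)
}

# isotropic Gaussian low-pass (sigma in pixels) via the FFT
smooth_raster <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  ny <- nrow(m); nx <- ncol(m)
  fx <- c(0:(nx %/% 2 - 1), -(nx - nx %/% 2):-1) / nx
  fy <- c(0:(ny %/% 2 - 1), -(ny - ny %/% 2):-1) / ny
  H <- exp(-2 * pi^2 * sigma_px^2 *
             (matrix(fx^2, ny, nx, byrow = TRUE) + matrix(fy^2, ny, nx)))
  Re(fft2(fft2(m + 0i) * H, inverse = TRUE))
}

#' Synthetic training pairs for the data-driven magnifier
#'
#' Generates `n` input/target raster pairs: inputs are seeded
#' `random_shapes` amplitude masks; each target is its input point-reflected
#' through the optical axis and scaled by `magnification` - the ideal
#' imaging map of a 4f relay with focal ratio `magnification`. The held-out
#' evaluation masks (`triangle`, `blob_logo`) are never used as training
#' inputs.
#'
#' Inputs are band-limited (a mild Gaussian low-pass of width
#' `smooth_frac` of the grid) so that the imaging task stays realizable by a
#' diffraction-limited relay: perfectly sharp binary edges could never be
#' reproduced by any physical system.
#'
#' @param n Number of pairs.
#' @param magnification Target magnification (e.g. 2).
#' @param grid An `ol_grid`.
#' @param seed Seed; pair `i` derives its own sub-seed.
#' @param smooth_frac Low-pass width as a fraction of the grid size
#'   (default 0.015).
#' @return List of `list(input =, target =)` matrices.
#' @export
make_4f_dataset <- function(n, magnification, grid, seed = 1L,
                            smooth_frac = 0.015) {
  stopifnot(n >= 1)
  sigma_px <- smooth_frac * min(grid$nx, grid$ny)
  # shapes are confined to the central region so the magnified image still
  # fits the camera window
  spread <- max(0.02, 0.25 / magnification - 0.07)
  lapply(seq_len(n), function(i) {
    inp <- smooth_raster(
      make_mask(grid, "random_shapes", size_fraction = 0.25,
                seed = seed * 1000L + i, spread = spread), sigma_px)
    # the input raster is an amplitude mask; the ground-truth camera image is
    # the imaged intensity |input|^2 under the ideal magnifying map
    list(input = inp, target = imaging_map(inp^2, grid, magnification))
  })
}

#' Simulate the ideal two-lens 4f relay
#'
#' Builds the reference magnifier: the input amplitude mask propagates a
#' focal length `f1` to a quadratic-phase element of focal `f1`, then
#' `f1 + f2` to a second element of focal `f2`, and finally `f2` to the
#' camera, all with the zoomed Rayleigh-Sommerfeld propagator on windows
#' congruent with the input grid. The relay images with magnification
#' `f2 / f1` and inversion.
#'
#' @param f1,f2 Focal lengths in micrometres.
#' @param mask Input amplitude raster on `grid`.
#' @param grid An `ol_grid`.
#' @param wavelength Wavelength in nanometres.
#' @return List with `image` (detected intensity), `magnification` (signed
#'   estimate from [estimate_magnification()]), `inverted`, and the output
#'   `field`.
#' @export
run_4f_reference <- function(f1, f2, mask, grid, wavelength = 650) {
  stopifnot(f1 > 0, f2 > 0)
  win <- window_from_grid(grid)
  f <- scalar_field(grid, mask + 0i, wavelength)
  f <- propagate_czt(f, f1, win)
  f$u <- f$u * exp(1i * lens_mask(grid, f1, wavelength)$values)
  f <- propagate_czt(f, f1 + f2, win)
  f$u <- f$u * exp(1i * lens_mask(grid, f2, wavelength)$values)
  f <- propagate_czt(f, f2, win)
  img <- Mod(f$u)^2
  est <- estimate_magnification(mask^2, img, grid)
  list(image = img, magnification = est$magnification,
       inverted = est$inverted, field = f)
}

#' Estimate lateral magnification between two intensity patterns
#'
#' A template-matching estimator: the input pattern is pushed through the
#' ideal imaging map (point reflection and scaling by a trial magnification
#' `m`) and correlated with the output; the reported magnification maximizes
#' that correlation over `m`. An initial bracket comes from the ratio of
#' intensity-weighted RMS radii (pixels below `threshold` of each pattern's
#' maximum ignored, suppressing diffraction tails). The sign (image
#' inversion) is decided by comparing the matched correlations at `+m` and
#' `-m`.
#'
#' @param i_in,i_out Non-negative intensity rasters on `grid`.
#' @param grid An `ol_grid`.
#' @param threshold Relative intensity cut for the bracketing moment
#'   estimate (default 0.02).
#' @return List with `magnification` (> 0), `inverted` (logical), and the
#'   matched `correlation`.
#' @export
estimate_magnification <- function(i_in, i_out, grid, threshold = 0.02) {
  rms_radius <- function(I) {
    I <- ifelse(I >= threshold * max(I), I, 0)
    X <- grid_xmat(grid); Y <- grid_ymat(grid)
    s <- sum(I)
    cx <- sum(I * X) / s; cy <- sum(I * Y) / s
    sqrt(sum(I * ((X - cx)^2 + (Y - cy)^2)) / s)
  }
  m0 <- rms_radius(i_out) / rms_radius(i_in)
  corr_with <- function(mag) {
    pred <- imaging_map(i_in, grid, mag)
    if (sum(pred) == 0) return(-1)
    suppressWarnings(stats::cor(as.numeric(pred), as.numeric(i_out)))
  }
  fit <- function(sign) {
    opt <- stats::optimize(function(m) -corr_with(sign * m),
                           interval = c(0.6 * m0, 1.7 * m0), tol = 1e-4)
    list(m = opt$minimum, corr = -opt$objective)
  }
  # imaging_map(+m) is the point-reflected (inverted) imaging; -m upright
  pos <- fit(1); neg <- fit(-1)
  best <- if (pos$corr >= neg$corr) pos else neg
  list(magnification = best$m, inverted = pos$corr >= neg$corr,
       correlation = best$corr)
}

# eager simulation of the two-SLM magnifier chain under a noise model
magnifier_simulate_noisy <- function(masks, zs, input, grid, wavelength, noise) {
  f <- scalar_field(grid, input + 0i, wavelength)
  f <- propagate_rs(f, zs[1])
  f$u <- f$u * mask_transmission(masks[[1]], grid, noise, salt = 1L)
  f <- propagate_rs(f, zs[2])
  f$u <- f$u * mask_transmission(masks[[2]], grid, noise, salt = 2L)
  f <- propagate_rs(f, zs[3])
  Mod(f$u)^2
}

#' Robustness protocol: imaging error under noise and misalignment
#'
#' Re-simulates a solved two-SLM imaging chain under each supplied noise
#' level and reports the mean squared error of the detected intensity
#' against the noiseless output, normalized by the mean squared noiseless
#' intensity.
#'
#' @param masks List of two phase rasters (the solved SLM patterns).
#' @param zs The three chain distances (micrometres).
#' @param input Input amplitude raster.
#' @param grid An `ol_grid`.
#' @param wavelength Wavelength in nanometres.
#' @param levels Named list of [noise_model()]s (e.g. `none`, `standard`,
#'   `stress`, `stress_8bit`).
#' @param seed Overrides every level's seed for reproducibility.
#' @return Data frame with columns `level` and `nmse`.
#' @export
run_robustness <- function(masks, zs, input, grid, wavelength = 650,
                           levels = list(none = noise_model(0),
                                         standard = noise_standard(),
                                         stress = noise_stress(),
                                         stress_8bit = noise_stress(eight_bit = TRUE)),
                           seed = 1L) {
  base <- suppressWarnings(
    magnifier_simulate_noisy(masks, zs, input, grid, wavelength, NULL))
  denom <- mean(base^2)
  nmse <- vapply(names(levels), function(nm) {
    nm_model <- levels[[nm]]
    nm_model$seed <- as.integer(seed)
    I <- suppressWarnings(
      magnifier_simulate_noisy(masks, zs, input, grid, wavelength, nm_model))
    mean((I - base)^2) / denom
  }, numeric(1))
  data.frame(level = names(levels), nmse = unname(nmse),
             stringsAsFactors = FALSE)
}
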