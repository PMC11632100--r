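# Scalar and vectorial free-space diffraction against closed-form oracles.

test_that("z = 0 is the identity and energy is conserved on contained fields", {
  g <- make_grid(96, 96, 1)
  src <- gaussian_source(g, 650, waist = 8)
  sf <- scalar_field(g, src$ex, 650)
  expect_lt(max(Mod(propagate_rs(sf, 0)$u - sf$u)), 1e-12)
  out <- quiet(propagate_rs(sf, 250))
  expect_lt(abs(field_power(out) / field_power(sf) - 1), 0.01)
  vout <- quiet(propagate_vrs(src, 250))
  expect_lt(abs(field_power(vout) / field_power(src) - 1), 0.01)
})

test_that("Gaussian beams spread per the closed-form w(z) within 1%", {
  g <- make_grid(128, 128, 1)
  w0 <- 8; lam <- 0.65; zr <- pi * w0^2 / lam
  src <- gaussian_source(g, 650, waist = w0)
  sf <- scalar_field(g, src$ex, 650)
  X <- matrix(g$x, g$ny, g$nx, byrow = TRUE); Y <- matrix(g$y, g$ny, g$nx)
  for (z in c(zr / 2, zr)) {
    I <- Mod(quiet(propagate_rs(sf, z))$u)^2
    w_meas <- sqrt(2 * sum(I * (X^2 + Y^2)) / sum(I))
    w_theory <- w0 * sqrt(1 + (z / zr)^2)
    expect_lt(abs(w_meas / w_theory - 1), 0.01)
  }
})

test_that("far-field of a circular aperture shows the Airy null at 1.22 lambda z / D", {
  g <- make_grid(512, 512, 1)
  D <- 48; lam <- 0.65; z <- 12000
  X <- matrix(g$x, g$ny, g$nx, byrow = TRUE); Y <- matrix(g$y, g$ny, g$nx)
  ap <- (X^2 + Y^2) <= (D / 2)^2
  sf <- scalar_field(g, ap + 0i, 650)
  I <- Mod(quiet(propagate_rs(sf, z))$u)^2
  prof <- I[which.min(abs(g$y)), ]
  xs <- g$x[g$x >= 0]; ps <- prof[g$x >= 0]
  # first local minimum of the radial profile
  i0 <- which(diff(sign(diff(ps))) > 0)[1] + 1L
  expect_lt(abs(xs[i0] / (1.22 * lam * z / D) - 1), 0.02)
})

test_that("CZT equals RS on congruent windows and handles zoom and z = 0", {
  g <- make_grid(128, 128, 1)
  src <- gaussian_source(g, 650, waist = 8)
  sf <- scalar_field(g, src$ex, 650)
  win <- window_from_grid(g)
  for (z in c(150, 400)) {
    a <- quiet(propagate_rs(sf, z))
    b <- quiet(propagate_czt(sf, z, win))
    expect_lt(max(Mod(a$u - b$u)) / max(Mod(a$u)), 1e-6)
  }
  idz <- propagate_czt(sf, 0, win)
  expect_lt(max(Mod(idz$u - sf$u)) / max(Mod(sf$u)), 1e-6)
  expect_error(output_window(64, 64, 0), "positive")
})

test_that("a lens-phased aperture focused via zoomed CZT gives the Airy FWHM", {
  g <- make_grid(256, 256, 1)
  lam <- 0.65; f <- 3000; D <- 180
  X <- matrix(g$x, g$ny, g$nx, byrow = TRUE); Y <- matrix(g$y, g$ny, g$nx)
  ap <- (X^2 + Y^2) <= (D / 2)^2
  u <- ap * exp(1i * lens_mask(g, f, 650)$values)
  foc <- quiet(propagate_czt(scalar_field(g, u, 650), f,
                             output_window(256, 256, 16, 16)))  # zoom x8
  m <- spot_metrics(Mod(foc$u)^2, foc$grid)
  expect_lt(abs(m$fwhm_x / (1.02899 * lam * f / D) - 1), 0.03)
})

test_that("the semigroup property holds for composed hops", {
  g <- make_grid(96, 96, 1)
  src <- gaussian_source(g, 650, waist = 8)
  sf <- scalar_field(g, src$ex, 650)
  z <- 300
  once <- quiet(propagate_rs(sf, z))
  twice <- quiet(propagate_rs(quiet(propagate_rs(sf, z / 2)), z / 2))
  expect_lt(max(Mod(once$u - twice$u)) / max(Mod(once$u)), 1e-4)
})

test_that("VRS decouples polarizations, matches the scalar limit, and is divergence-free", {
  g <- make_grid(128, 128, 1)
  src <- gaussian_source(g, 650, waist = 10)
  out <- quiet(propagate_vrs(src, 400))
  expect_true(all(out$ey == 0))
  sc <- quiet(propagate_rs(scalar_field(g, src$ex, 650), 400))
  expect_lt(max(Mod(out$ex - sc$u)) / max(Mod(sc$u)), 1e-3)
  # spectral divergence residual over the propagating region
  k <- 2 * pi / 0.65
  fx <- fft(out$ex); fy <- fft(out$ey); fz <- fft(out$ez)
  kv <- 2 * pi / (g$nx * g$pitch[1]) * c(0:(g$nx / 2 - 1), -(g$nx / 2):-1)
  KX <- matrix(kv, g$ny, g$nx, byrow = TRUE); KY <- matrix(kv, g$ny, g$nx)
  kz2 <- k^2 - KX^2 - KY^2
  m <- kz2 > 0
  KZ <- sqrt(pmax(kz2, 0))
  resid <- sqrt(sum(Mod(KX * fx + KY * fy + KZ * fz)[m]^2))
  nrm <- sqrt(sum((k * sqrt(Mod(fx)^2 + Mod(fy)^2 + Mod(fz)^2))[m]^2))
  expect_lt(resid / nrm, 1e-3)
  # longitudinal component vanishes in the deep paraxial limit
  expect_lt(max(Mod(out$ez)) / max(Mod(out$ex)), 0.05)
  expect_error(propagate_vrs(out, 100), "transverse")
})

test_that("VCZT matches VRS componentwise on congruent windows", {
  g <- make_grid(96, 96, 1)
  src <- gaussian_source(g, 650, waist = 8)
  win <- window_from_grid(g)
  a <- quiet(propagate_vrs(src, 300))
  b <- quiet(propagate_vczt(src, 300, win))
  for (comp in c("ex", "ey", "ez"))
    expect_lt(max(Mod(a[[comp]] - b[[comp]])) / max(Mod(a$ex)), 1e-6)
})

test_that("high-NA focusing reproduces the classic vectorial focal fields", {
  g <- make_grid(128, 128, 20)
  f <- 1350
  X <- matrix(g$x, g$ny, g$nx, byrow = TRUE); Y <- matrix(g$y, g$ny, g$nx)
  rho <- sqrt(X^2 + Y^2); phi <- atan2(Y, X)
  # radially polarized doughnut pupil: on-axis |Ez|^2 is the focal maximum
  amp <- exp(-(rho / 900)^2) * (rho / 900)
  pup <- vector_field(g, amp * cos(phi) + 0i, amp * sin(phi) + 0i,
                      wavelength = 650)
  foc <- focus_high_na(pup, 0.9, f, output_window(65, 65, 2, 2))
  Iz <- field_intensity(foc, "longitudinal")
  It <- field_intensity(foc, "transverse")
  ctr <- c(which.min(abs(foc$grid$y)), which.min(abs(foc$grid$x)))
  expect_equal(Iz[ctr[1], ctr[2]], max(Iz), tolerance = 1e-6)
  expect_lt(It[ctr[1], ctr[2]] / max(It), 0.05)
  # x-polarized pupil: focal spot elongated along x
  pupx <- vector_field(g, exp(-(rho / 700)^2) + 0i, wavelength = 650)
  focx <- focus_high_na(pupx, 0.9, f, output_window(64, 64, 2, 2))
  mx <- spot_metrics(field_intensity(focx, "total"), focx$grid)
  expect_gt(mx$fwhm_x, mx$fwhm_y)
  # paraxial limit converges to the scalar Airy profile (aperture radius
  # f2 * NA must stay inside the pupil raster)
  f2 <- 24000
  pupu <- vector_field(g, (rho <= f2 * 0.05) + 0i, wavelength = 650)
  focu <- focus_high_na(pupu, 0.05, f2, output_window(128, 128, 40, 40))
  mu <- spot_metrics(field_intensity(focu, "total"), focu$grid)
  expect_lt(abs(mu$fwhm_x / (0.5145 * 0.65 / 0.05) - 1), 0.02)
  expect_error(focus_high_na(pupx, 1.1, f, output_window(16, 16, 2)), "refractive")
})

test_that("back-propagation inverts forward propagation without evanescent gain", {
  g <- make_grid(96, 96, 1)
  src <- gaussian_source(g, 650, waist = 10)
  sf <- scalar_field(g, src$ex, 650)
  back <- quiet(propagate_rs(quiet(propagate_rs(sf, 300)), -300))
  expect_lt(max(Mod(back$u - sf$u)) / max(Mod(sf$u)), 1e-3)
  expect_lte(field_power(back), field_power(sf) * (1 + 1e-6))
})
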