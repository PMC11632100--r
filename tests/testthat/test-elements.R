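# Parametric optical elements and their imperfection models.

test_that("SLMs are pure phase elements: identity at zero mask, power conserved", {
  g <- make_grid(32, 32, 2)
  src <- gaussian_source(g, 650, waist = 12)
  zero <- phase_mask(matrix(0, 32, 32), g)
  out <- apply_slm(src, zero, "both")
  expect_equal(out$ex, src$ex)
  sp <- spiral_mask(g, 1)
  outs <- apply_slm(src, sp, "H")
  expect_equal(Mod(outs$ex), Mod(src$ex), tolerance = 1e-12)
  expect_lt(abs(field_power(outs) - field_power(src)), 1e-10)
  # phase of ex advanced by the azimuthal angle
  X <- matrix(g$x, 32, 32, byrow = TRUE); Y <- matrix(g$y, 32, 32)
  dphi <- wrap_phase(Arg(outs$ex) - Arg(src$ex) - atan2(Y, X))
  expect_lt(max(abs(dphi)), 1e-9)
  expect_error(apply_slm(src, phase_mask(matrix(0, 16, 16), make_grid(16, 16, 2))),
               "grid")
})

test_that("the super-SLM addresses H and V independently and audits as 2 panels", {
  g <- make_grid(32, 32, 2)
  src <- gaussian_source(g, 650, waist = 12,
                         polarization = c(1, 1) / sqrt(2))
  sp <- spiral_mask(g, 1); zero <- phase_mask(matrix(0, 32, 32), g)
  out <- super_slm(src, sp, zero)
  expect_equal(out$ey, src$ey)
  expect_false(isTRUE(all.equal(out$ex, src$ex)))
  # equal masks degenerate to a scalar phase on both components
  both <- super_slm(src, sp, sp)
  ref <- apply_slm(src, sp, "both")
  expect_equal(both$ex, ref$ex)
  expect_equal(both$ey, ref$ey)
  a <- build_ansatz(ansatz_spec(3, 3))
  expect_identical(a$audit$slm_panels, 2L * a$audit$sslm)
})

test_that("wave plates implement the Jones retarder exactly", {
  g <- make_grid(16, 16, 2)
  src <- gaussian_source(g, 650, waist = 10)
  # eta = 0: identity up to global phase
  out0 <- wave_plate(src, wave_plate_params(0, 0.7))
  expect_lt(max(Mod(out0$ex - src$ex)), 1e-12)
  # half-wave plate at 45 deg flips x to y
  outh <- wave_plate(src, wave_plate_params(pi, pi / 4))
  expect_lt(max(Mod(outh$ex)), 1e-10)
  expect_equal(Mod(outh$ey), Mod(src$ex), tolerance = 1e-10)
  # quarter-wave plate at 45 deg gives circular polarization
  outq <- wave_plate(src, wave_plate_params(pi / 2, pi / 4))
  expect_equal(Mod(outq$ex), Mod(outq$ey), tolerance = 1e-10)
  nz <- Mod(src$ex) > 1e-6 * max(Mod(src$ex))
  rel <- wrap_phase(Arg(outq$ey[nz]) - Arg(outq$ex[nz]))
  expect_lt(max(abs(abs(rel) - pi / 2)), 1e-10)
  expect_lt(abs(field_power(outq) - field_power(src)), 1e-10)
})

test_that("beam splitters are unitary and reproduce the Mach-Zehnder", {
  g <- make_grid(16, 16, 2)
  a <- gaussian_source(g, 650, waist = 10)
  b <- gaussian_source(g, 650, waist = 6)
  # fully transmissive
  full <- beam_splitter(a, NULL, beam_splitter_params(1))
  expect_equal(full$c$ex, a$ex, tolerance = 1e-12)
  expect_lt(field_power(full$d), 1e-20)
  # unitarity for arbitrary lossless splits
  for (t in c(0.2, 0.5, 0.83)) {
    o <- beam_splitter(a, b, beam_splitter_params(t))
    expect_lt(abs(field_power(o$c) + field_power(o$d) -
                    field_power(a) - field_power(b)), 1e-10)
  }
  # balanced Mach-Zehnder with equal arms: all power exits one port
  bs <- beam_splitter_params(0.5)
  s1 <- beam_splitter(a, NULL, bs)
  s2 <- beam_splitter(s1$c, s1$d, bs)
  ptot <- field_power(s2$c) + field_power(s2$d)
  expect_gt(field_power(s2$d) / ptot, 0.999)
  expect_error(beam_splitter_params(0.7, 0.5), "T \\+ R")
  # polarizing variant: H transmits, V reflects, power conserved
  d <- gaussian_source(g, 650, waist = 8, polarization = c(1, 1) / sqrt(2))
  pol <- beam_splitter(d, NULL, bs, polarizing = TRUE)
  expect_equal(pol$c$ex, d$ex)
  expect_lt(max(Mod(pol$c$ey)), 1e-20)
  expect_equal(Mod(pol$d$ey), Mod(d$ey), tolerance = 1e-12)
  expect_lt(abs(field_power(pol$c) + field_power(pol$d) - field_power(d)), 1e-10)
})

test_that("canonical masks: spiral charge 0 and infinite-focal lens are empty", {
  g <- make_grid(32, 32, 2)
  expect_true(all(spiral_mask(g, 0)$values == 0))
  expect_true(all(lens_mask(g, Inf, 650)$values == 0))
  lm <- lens_mask(g, 5000, 650)
  k <- 2 * pi / 0.65
  expect_equal(lm$values[17, 20], wrap_phase(-k * (g$x[20]^2 + g$y[17]^2) / 1e4),
               tolerance = 1e-12)
})

test_that("a focused spiral-phase beam carries an on-axis null", {
  g <- make_grid(128, 128, 1)
  src <- gaussian_source(g, 650, waist = 20)
  v <- apply_slm(src, spiral_mask(g, 1), "both")
  u <- v$ex * exp(1i * lens_mask(g, 4000, 650)$values)
  foc <- quiet(propagate_czt(scalar_field(g, u, 650), 4000,
                             output_window(97, 97, 30, 30)))  # odd: a pixel sits on the axis
  I <- Mod(foc$u)^2
  ctr <- c(which.min(abs(foc$grid$y)), which.min(abs(foc$grid$x)))
  expect_lt(I[ctr[1], ctr[2]] / max(I), 1e-4)
})

test_that("the radial converter produces radial polarization and a tight Ez focus", {
  g <- make_grid(65, 65, 30)  # odd: the singular axis pixel exists
  src <- gaussian_source(g, 650, waist = 500)
  out <- radial_converter(src)
  X <- matrix(g$x, 65, 65, byrow = TRUE); Y <- matrix(g$y, 65, 65)
  phi <- atan2(Y, X)
  nz <- Mod(src$ex) > 1e-3 * max(Mod(src$ex)) & sqrt(X^2 + Y^2) > 30
  expect_lt(max(Mod(out$ex[nz] - cos(phi[nz]) * Mod(src$ex[nz]) *
                      exp(1i * Arg(src$ex[nz])))), 1e-9)
  expect_lt(max(Mod(out$ey[nz] - sin(phi[nz]) * Mod(src$ex[nz]) *
                      exp(1i * Arg(src$ex[nz])))), 1e-9)
  # singular on-axis pixel zeroed
  ctr <- c(which.min(abs(g$y)), which.min(abs(g$x)))
  expect_equal(Mod(out$ex[ctr[1], ctr[2]]), 0)
  # tight focus of the converted beam maximizes |Ez|^2 on axis
  foc <- focus_high_na(out, 0.9, 1000, output_window(49, 49, 2, 2))
  Iz <- field_intensity(foc, "longitudinal")
  c2 <- c(which.min(abs(foc$grid$y)), which.min(abs(foc$grid$x)))
  expect_equal(Iz[c2[1], c2[2]], max(Iz), tolerance = 1e-6)
})

test_that("noise models are seed-reproducible and quantization is optional", {
  g <- make_grid(32, 32, 2)
  src <- gaussian_source(g, 650, waist = 12)
  sp <- spiral_mask(g, 1)
  nm <- noise_model(phase_noise = 0.1, misalign = 0.1, seed = 7L)
  o1 <- apply_slm(src, sp, "both", nm)
  o2 <- apply_slm(src, sp, "both", nm)
  expect_identical(o1$ex, o2$ex)
  o3 <- apply_slm(src, sp, "both", noise_model(0.1, 0.1, seed = 8L))
  expect_false(isTRUE(all.equal(o1$ex, o3$ex)))
  # 8-bit quantization moves phases by at most half a level
  nq <- noise_model(quantize_bits = 8L, seed = 1L)
  oq <- apply_slm(src, sp, "both", nq)
  dphi <- wrap_phase(Arg(oq$ex) - Arg(src$ex)) - sp$values
  expect_lt(max(abs(wrap_phase(dphi))), pi / 2^8 + 1e-9)
  # noise draws leave the global RNG stream untouched
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(apply_slm(src, sp, "both", nm)); after <- runif(1)
  expect_identical(before, after)
})
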