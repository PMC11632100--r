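# Loss functions, detector statistics and the depletion model.

test_that("density loss matches the analytic uniform and delta cases", {
  expect_equal(density_loss(matrix(1, 8, 8), loss_config(epsilon = 0.5)), 1.0)
  m <- matrix(0, 8, 8); m[4, 5] <- 10
  expect_equal(density_loss(m, loss_config(epsilon = 0.5)), 0.1)
  expect_error(density_loss(matrix(0, 4, 4)), "no signal")
  expect_error(density_loss(matrix(-1, 4, 4)), "non-negative")
})

test_that("density loss equals the explicit per-pixel loop oracle", {
  set.seed(42)
  for (eps in c(0.2, 0.5, 0.8)) {
    r <- matrix(runif(32 * 32), 32, 32)
    expect_equal(density_loss(r, loss_config(epsilon = eps)),
                 density_loss_loop(r, eps), tolerance = 1e-12)
  }
})

test_that("density loss is scale-invariant and rewards concentration", {
  set.seed(7)
  r <- matrix(runif(16 * 16), 16, 16)
  cfg <- loss_config(epsilon = 0.4)
  l <- density_loss(r, cfg)
  for (c in c(0.1, 3, 1e4))
    expect_equal(density_loss(c * r, cfg), l / c, tolerance = 1e-12)
  # moving intensity from a dim above-threshold pixel onto the brightest
  # pixel never increases the loss
  for (i in 1:20) {
    r2 <- matrix(runif(16 * 16), 16, 16)
    st <- r2 > 0.5 * max(r2)
    dims <- which(st & r2 < 0.8 * max(r2))
    if (length(dims) == 0) next
    donor <- dims[1]
    r3 <- r2
    r3[which.max(r2)] <- r3[which.max(r2)] + r2[donor]
    r3[donor] <- 0
    expect_lte(density_loss(r3, cfg), density_loss(r2, cfg) + 1e-12)
  }
})

test_that("density loss gradient matches finite differences off threshold ties", {
  set.seed(3)
  r <- matrix(runif(12 * 12, 0.1, 1), 12, 12)
  cfg <- loss_config(epsilon = 0.5)
  g <- density_loss_grad(r, cfg)
  st <- density_stats(r, cfg)
  probe <- sample(which(abs(r - st$thr) > 0.05 & r != max(r)), 6)
  for (i in probe) {
    h <- 1e-6
    rp <- r; rp[i] <- rp[i] + h
    rm <- r; rm[i] <- rm[i] - h
    fd <- (density_loss(rp, cfg) - density_loss(rm, cfg)) / (2 * h)
    if (abs(fd) < 1e-12) expect_lt(abs(g[i]), 1e-10)
    else expect_lt(abs(g[i] - fd) / abs(fd), 1e-4)
  }
})

test_that("softmin matches its closed form, bounds, and sharp limit", {
  expect_equal(softmin(3.7, 10), 3.7)
  expect_equal(softmin(c(1, 2), 10), 1 - log(1 + exp(-10)) / 10,
               tolerance = 1e-12)
  expect_equal(softmin(c(1, 2), 10), 0.9999954601100783, tolerance = 1e-10)
  set.seed(11)
  for (i in 1:1000) {
    l <- runif(sample(2:6, 1), 0, 10)
    b <- runif(1, 0.5, 50)
    s <- softmin(l, b)
    expect_lte(s, min(l) + 1e-12)
    expect_gte(s, min(l) - log(length(l)) / b - 1e-12)
  }
  l <- c(0.3, 0.9, 2)
  expect_equal(softmin(l, 1e6), min(l), tolerance = 1e-5)
  expect_error(softmin(numeric(0)), "at least one")
  w <- softmin_weights(c(1, 1.02, 5), 100)
  expect_equal(sum(w), 1)
  expect_gt(w[1], w[2])
})

test_that("MSE loss matches its trivial cases and the loop oracle", {
  a <- matrix(runif(64), 8, 8)
  expect_equal(mse_loss(a, a), 0)
  expect_equal(mse_loss(a + 0.3, a), 0.09, tolerance = 1e-12)
  b <- matrix(runif(64), 8, 8)
  expect_equal(mse_loss(a, b), mse_loop(a, b), tolerance = 1e-12)
  expect_error(mse_loss(a, matrix(0, 4, 4)), "shape")
})

test_that("the Beer-Lambert effective beam narrows with depletion strength", {
  g <- make_grid(97, 97, 0.25)  # odd: exact on-axis sample
  exc <- gaussian_raster(g, 3)
  X <- matrix(g$x, g$ny, g$nx, byrow = TRUE); Y <- matrix(g$y, g$ny, g$nx)
  r2 <- X^2 + Y^2
  dep <- r2 * exp(-r2 / 18)  # doughnut
  expect_equal(sted_effective(exc, matrix(0, g$ny, g$nx)), exc)
  f0 <- spot_metrics(exc, g)$fwhm_x
  last <- f0
  for (alpha in c(2, 10, 50)) {
    eff <- sted_effective(exc, dep, sted_params(alpha = alpha))
    fw <- spot_metrics(eff, g, center = "axis")$fwhm_x
    expect_lt(fw, last)   # monotone shrinkage in alpha
    last <- fw
  }
  expect_lt(last, f0 / 3)  # clearly sub-diffraction at alpha = 50
  # 1-D radial numerical oracle: effective radial profile crosses half max
  # where exc * exp(-alpha*dep/max) does
  rr <- seq(0, 12, by = 1e-3)
  excr <- exp(-rr^2 / (2 * 9))
  depr <- rr^2 * exp(-rr^2 / 18); depr <- depr / max(depr)
  effr <- excr * exp(-10 * depr)
  r_half <- rr[which(effr < effr[1] / 2)[1]]
  eff10 <- sted_effective(exc, dep, sted_params(alpha = 10))
  expect_equal(spot_metrics(eff10, g, center = "axis")$fwhm_x / 2, r_half,
               tolerance = 0.02)
  expect_error(sted_effective(-exc, dep), "non-negative")
})

test_that("detect() selects the advertised intensity components", {
  g <- make_grid(24, 24, 1)
  f <- vector_field(g,
                    ex = matrix(1 + 1i, 24, 24), ey = matrix(0.5 + 0i, 24, 24),
                    ez = matrix(0 + 2i, 24, 24), wavelength = 650)
  tr <- detect(f, "transverse"); lg <- detect(f, "longitudinal")
  tt <- detect(f, "total")
  expect_equal(tr$i_det[1, 1], 2.25)
  expect_equal(lg$i_det[1, 1], 4)
  expect_equal(tt$i_det, tr$i_det + lg$i_det)
  # paraxial x-polarized fields carry no longitudinal intensity
  src <- gaussian_source(g, 650, waist = 8)
  expect_equal(max(detect(src, "longitudinal")$i_det), 0)
})
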