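# Shared fixtures, built in code at test time.

quiet <- function(expr) suppressWarnings(expr)

# isotropic Gaussian intensity raster with given sigma (um)
gaussian_raster <- function(grid, sigma, center = c(0, 0)) {
  X <- matrix(grid$x, grid$ny, grid$nx, byrow = TRUE)
  Y <- matrix(grid$y, grid$ny, grid$nx)
  exp(-((X - center[1])^2 + (Y - center[2])^2) / (2 * sigma^2))
}

# brute-force per-pixel implementation of the density loss (the independent
# oracle for the vectorized version): explicit double loop over pixels
density_loss_loop <- function(i_det, epsilon) {
  i_max <- max(i_det)
  thr <- epsilon * i_max
  I_eps <- 0; area <- 0
  for (k in seq_len(nrow(i_det))) {
    for (l in seq_len(ncol(i_det))) {
      if (i_det[k, l] > thr) {
        I_eps <- I_eps + i_det[k, l]
        area <- area + 1
      }
    }
  }
  area / I_eps
}

# explicit-loop mean squared error oracle
mse_loop <- function(a, b) {
  s <- 0
  for (i in seq_along(a)) s <- s + (a[i] - b[i])^2
  s / length(a)
}

# a small 2x2 test ansatz with two sources and two detectors
small_ansatz <- function(mode = "full", nx = 32) {
  g <- make_grid(nx, nx, 1280 / nx)
  spec <- ansatz_spec(2, 2, grid = g, mode = mode,
    sources = list(
      list(port = "S1", wavelength = 650, polarization = c(1, 0), waist = 300),
      list(port = "W2", wavelength = 532, polarization = c(1, 0), waist = 300)),
    detectors = list(
      list(port = "N1", na = 0.9, nx = 24L, extent = 3, focal = NULL),
      list(port = "N2", na = 0.9, nx = 24L, extent = 3, focal = NULL)))
  build_ansatz(spec)
}
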