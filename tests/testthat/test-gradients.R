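# Adjoint-engine gradients against central finite differences.

test_that("gradients flow correctly through a 2-element toy setup", {
  set.seed(7)
  g <- make_grid(32, 32, 1)
  src <- gaussian_source(g, 650, waist = 5)
  mask0 <- matrix(runif(32 * 32, -0.3, 0.3), 32, 32)
  cfg <- loss_config(epsilon = 0.3)
  # SLM phase -> wave plate -> propagation -> splitter -> density loss
  loss_fn <- function(theta) {
    mask <- matrix(theta[1:1024], 32, 32)
    z <- theta[1025]; eta <- theta[1026]; th <- theta[1027]; t <- theta[1028]
    tape <- tape_new()
    exid <- tp_phase(tape, tp_leaf(tape, src$ex), mask, pname = "mask")
    eyid <- tp_leaf(tape, src$ey)
    jj <- tp_jones(tape, exid, eyid, eta, th,
                   eta_name = "eta", theta_name = "theta")
    prep <- rs_prep(g, 650, z, c("z", "dz"))
    px <- tp_prop(tape, jj$ex, prep, "z")
    py <- tp_prop(tape, jj$ey, prep, "z")
    bs <- tp_bs(tape, list(ex = px, ey = py), NULL, t, "t")
    ids <- list(bs$c$ex, bs$c$ey)
    I <- Mod(tp_val(tape, ids[[1]]))^2 + Mod(tp_val(tape, ids[[2]]))^2
    w <- density_loss_grad(I, cfg)
    pg <- tape_backward(tape, intensity_seeds(tape, ids, w))
    grad <- c(as.numeric(pg$mask), pg$z, pg$eta %||% 0, pg$theta %||% 0, pg$t)
    list(value = density_loss(I, cfg), grad = grad)
  }
  theta <- c(as.numeric(mask0), 150, 0.7, 0.4, 0.6)
  err <- grad_check(loss_fn, theta, n_probes = 12, h = 1e-3, seed = 5)
  expect_lt(err, 1e-4)
  # a parameter the loss cannot depend on has exactly zero gradient:
  # the total transmitted intensity is invariant under the unitary wave
  # plate, so d/d eta vanishes identically
  r <- loss_fn(theta)
  expect_equal(r$grad[1026], 0, tolerance = 1e-10)
})

test_that("MSE through the 4f chain is differentiable in the three distances", {
  g <- make_grid(32, 32, 8)
  tri <- make_mask(g, "triangle", size_fraction = 0.4)
  target <- imaging_map(tri, g, 2)
  target_n <- target / sum(target)
  lens1 <- lens_mask(g, 4000, 650)$values
  lens2 <- lens_mask(g, 8000, 650)$values
  loss_fn <- function(zs) {
    tape <- tape_new()
    out <- magnifier_forward(tape, tri, list(lens1, lens2), zs, g, 650,
                             z_names = c("za", "zb", "zc"))
    I <- Mod(tp_val(tape, out))^2
    nm <- normalized_mse(I, target_n)
    pg <- tape_backward(tape, intensity_seeds(tape, list(out), nm$w))
    list(value = nm$value, grad = c(pg$za, pg$zb, pg$zc))
  }
  err <- grad_check(loss_fn, c(4000, 12000, 8000), n_probes = 3, h = 1e-4,
                    seed = 2)
  expect_lt(err, 1e-4)
})

test_that("every ansatz parameter family receives a correct gradient", {
  a <- small_ansatz()
  act <- active_params(a, bs = TRUE, z1 = TRUE, z2 = TRUE, wp = TRUE,
                       slm = c(1L, 2L))
  th <- ansatz_init_fn(a, act, z_range = c(5e3, 5e4), z_default = 2e4)(42)
  obj <- ansatz_objective(a, act, loss_config(epsilon = 0.5), "transverse")
  err <- grad_check(obj, th, n_probes = 14, h = 1e-5, seed = 3)
  expect_lt(err, 1e-4)
})

test_that("the STED effective-beam objective is differentiable", {
  a <- small_ansatz()
  act <- active_params(a, bs = TRUE, z1 = c(1L, 2L), wp = c(1L, 2L))
  th <- ansatz_init_fn(a, act, z_range = c(5e3, 5e4), z_default = 2e4)(9)
  obj <- ansatz_objective(a, act, loss_config(epsilon = 0.5), "transverse",
                          sted = list(params = sted_params(alpha = 10),
                                      excitation = 650, depletion = 532))
  err <- grad_check(obj, th, n_probes = 8, h = 1e-5, seed = 4)
  expect_lt(err, 1e-3)  # the frozen depletion normalization is piecewise
})

test_that("adjoints of the zoomed transforms match their forward operators", {
  # <A x, y> == <x, A^H y> for the focusing transform
  g <- make_grid(24, 24, 40)
  fp <- focus_prep(g, 650, 0.9, 500)
  win <- output_window(16, 16, 2, 2)
  set.seed(1)
  x <- matrix(complex(real = rnorm(24 * 24), imaginary = rnorm(24 * 24)), 24, 24)
  y <- matrix(complex(real = rnorm(16 * 16), imaginary = rnorm(16 * 16)), 16, 16)
  lhs <- sum(Conj(y) * focus_transform(x, fp, win))
  rhs <- sum(Conj(focus_transform_adjoint(y, fp, win)) * x)
  expect_lt(Mod(lhs - rhs) / Mod(lhs), 1e-10)
  # and for the zoomed RS evaluation
  prep <- rs_prep(g, 650, 3e4, "z")
  V <- matrix(complex(real = rnorm(prep$py * prep$px),
                      imaginary = rnorm(prep$py * prep$px)), prep$py, prep$px)
  lhs2 <- sum(Conj(y) * czt_evaluate(V, prep, win))
  rhs2 <- sum(Conj(czt_evaluate_adjoint(y, prep, win)) * V)
  expect_lt(Mod(lhs2 - rhs2) / Mod(lhs2), 1e-10)
})
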