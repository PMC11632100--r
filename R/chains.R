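# Differentiable objectives over simple sequential ("chain") setups: the
# single-SLM focusing task and the two-SLM 4f magnifier trained on
# input/target image pairs.

chain_index <- function(...) {
  segs <- list(); off <- 0
  for (s in list(...)) {
    segs[[length(segs) + 1L]] <- list(family = s$family, idx = s$idx,
                                      offset = off, len = s$len)
    off <- off + s$len
  }
  segs
}

seg_slice <- function(theta, segs, family, idx) {
  for (s in segs)
    if (s$family == family && s$idx == idx)
      return(theta[s$offset + seq_len(s$len)])
  stop("missing parameter segment ", family, "_", idx)
}

#' Differentiable single-SLM focusing objective
#'
#' The elementary design task: one programmable phase raster reshapes a
#' Gaussian beam so that, after a free-space hop of `z` micrometres, the
#' detected intensity concentrates into a tight spot. The objective is the
#' inverse-density loss of the detected intensity; its known minimizer is a
#' lens-like quadratic phase.
#'
#' @param grid Computational `ol_grid`.
#' @param wavelength Source wavelength in nanometres.
#' @param z Propagation distance to the detector (micrometres).
#' @param waist Source waist (micrometres; default grid half-width / 4).
#' @param cfg An [loss_config()].
#' @return List with `objective` (a `loss_fn` for [optimize_setup()]),
#'   `init` (flat zero-phase parameter vector with packing index), and
#'   `simulate(theta)` returning the detected intensity raster.
#' @export
slm_focus_task <- function(grid, wavelength = 650, z = 5e4, waist = NULL,
                           cfg = loss_config()) {
  src <- gaussian_source(grid, wavelength, waist = waist)
  n <- grid$nx * grid$ny
  init <- numeric(n)
  attr(init, "index") <- chain_index(list(family = "slm_h", idx = 1L, len = n))
  prep <- rs_prep(grid, wavelength, z, "z")
  forward <- function(theta, tape) {
    mask <- matrix(as.numeric(theta), grid$ny, grid$nx)
    id <- tp_leaf(tape, src$ex)
    id <- tp_phase(tape, id, mask, pname = "slm_h_1")
    tp_prop(tape, id, prep)
  }
  objective <- function(theta) {
    tape <- tape_new()
    id <- forward(theta, tape)
    I <- Mod(tp_val(tape, id))^2
    value <- density_loss(I, cfg)
    w <- density_loss_grad(I, cfg)
    pgrad <- tape_backward(tape, intensity_seeds(tape, list(id), w))
    g <- numeric(length(theta))
    g[] <- as.numeric(pgrad[["slm_h_1"]])
    list(value = value, grad = g)
  }
  simulate <- function(theta) {
    tape <- tape_new()
    id <- forward(theta, tape)
    Mod(tp_val(tape, id))^2
  }
  list(objective = objective, init = init, simulate = simulate, grid = grid)
}

# forward pass of the two-SLM magnifier chain on the adjoint tape:
# input amplitude -> z1 -> SLM#1 -> z2 -> SLM#2 -> z3 -> detector
magnifier_forward <- function(tape, input_amp, masks, zs, grid, wavelength,
                              z_names = NULL, mask_names = NULL) {
  id <- tp_leaf(tape, input_amp + 0i)
  preps <- lapply(seq_along(zs), function(i)
    rs_prep(grid, wavelength, zs[i],
            if (!is.null(z_names)) c("z", "dz") else "z"))
  id <- tp_prop(tape, id, preps[[1]], z_names[1])
  id <- tp_phase(tape, id, masks[[1]], pname = mask_names[1])
  id <- tp_prop(tape, id, preps[[2]], z_names[2])
  id <- tp_phase(tape, id, masks[[2]], pname = mask_names[2])
  tp_prop(tape, id, preps[[3]], z_names[3])
}

# normalized-intensity MSE and its gradient w.r.t. the raw intensity raster
normalized_mse <- function(I, target_n) {
  s <- sum(I)
  b <- I / s
  d <- b - target_n
  value <- mean(d^2)
  w <- (2 / (length(I) * s)) * (d - sum(d * b))
  list(value = value, w = w)
}

#' Data-driven 4f magnifier training task
#'
#' Builds the differentiable two-SLM imaging chain of the magnifier
#' rediscovery: a collimated input mask propagates over `z1`, meets SLM#1,
#' propagates over `z2` to SLM#2, and over `z3` to the camera. The trainable
#' parameters are the two phase rasters and the three distances. The
#' objective for one batch is the mean, over its input/target pairs, of the
#' mean squared error between the detected and target intensity patterns
#' (both normalized to unit total intensity, making the loss scale-free).
#'
#' @param dataset List of `list(input =, target =)` rasters from
#'   [make_4f_dataset()].
#' @param grid The `ol_grid` shared by the chain.
#' @param wavelength Wavelength in nanometres.
#' @param batch Batch size (pairs per gradient step).
#' @param z_init Initial distances `c(z1, z2, z3)` in micrometres.
#' @param seed Seed for batch shuffling and mask initialization.
#' @return List with `objective`, `init`, `init_fn(seed)` (random phase
#'   rasters, distances jittered), `simulate(theta, input)` and
#'   `pair_losses(theta, pairs)`.
#' @export
magnifier_task <- function(dataset, grid, wavelength = 650, batch = 10,
                           z_init = NULL, seed = 1L) {
  stopifnot(length(dataset) >= 1)
  n <- grid$nx * grid$ny
  if (is.null(z_init)) {
    width <- grid$nx * grid$pitch[1]
    z_init <- rep(2 * width^2 / (grid$nx * wavelength_um(wavelength)), 3)
  }
  segs <- chain_index(list(family = "slm_h", idx = 1L, len = n),
                      list(family = "slm_h", idx = 2L, len = n),
                      list(family = "z1", idx = 1L, len = 3L))
  init <- c(numeric(2 * n), z_init)
  attr(init, "index") <- segs
  targets_n <- lapply(dataset, function(p) p$target / sum(p$target))

  order_env <- new.env(parent = emptyenv())
  order_env$queue <- integer(0)
  order_env$epoch <- 0L
  next_batch <- function() {
    idx <- integer(0)
    while (length(idx) < batch) {
      if (length(order_env$queue) == 0L) {
        order_env$epoch <- order_env$epoch + 1L
        old <- if (exists(".Random.seed", globalenv()))
          get(".Random.seed", globalenv()) else NULL
        set.seed(seed + order_env$epoch)
        order_env$queue <- sample(length(dataset))
        if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
      }
      take <- min(batch - length(idx), length(order_env$queue))
      idx <- c(idx, order_env$queue[seq_len(take)])
      order_env$queue <- order_env$queue[-seq_len(take)]
    }
    idx
  }

  unpack <- function(theta) {
    list(masks = list(matrix(seg_slice(theta, segs, "slm_h", 1), grid$ny, grid$nx),
                      matrix(seg_slice(theta, segs, "slm_h", 2), grid$ny, grid$nx)),
         zs = seg_slice(theta, segs, "z1", 1))
  }

  objective <- function(theta) {
    p <- unpack(theta)
    idx <- next_batch()
    total <- 0
    gacc <- numeric(length(theta))
    for (i in idx) {
      tape <- tape_new()
      out <- magnifier_forward(tape, dataset[[i]]$input, p$masks, p$zs,
                               grid, wavelength,
                               z_names = c("z1_a", "z1_b", "z1_c"),
                               mask_names = c("m1", "m2"))
      I <- Mod(tp_val(tape, out))^2
      nm <- normalized_mse(I, targets_n[[i]])
      total <- total + nm$value
      pg <- tape_backward(tape, intensity_seeds(tape, list(out), nm$w))
      gi <- c(as.numeric(pg[["m1"]] %||% numeric(n)),
              as.numeric(pg[["m2"]] %||% numeric(n)),
              pg[["z1_a"]] %||% 0, pg[["z1_b"]] %||% 0, pg[["z1_c"]] %||% 0)
      gacc <- gacc + gi
    }
    list(value = total / length(idx), grad = gacc / length(idx))
  }

  init_fn <- function(s) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    set.seed(s)
    out <- c(stats::runif(2 * n, -pi, pi), z_init * stats::runif(3, 0.5, 1.5))
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    attributes(out) <- attributes(init)
    out
  }

  simulate <- function(theta, input) {
    p <- unpack(theta)
    tape <- tape_new()
    out <- magnifier_forward(tape, input, p$masks, p$zs, grid, wavelength)
    Mod(tp_val(tape, out))^2
  }

  pair_losses <- function(theta, pairs) {
    vapply(pairs, function(pr) {
      I <- simulate(theta, pr$input)
      normalized_mse(I, pr$target / sum(pr$target))$value
    }, numeric(1))
  }

  list(objective = objective, init = init, init_fn = init_fn,
       simulate = simulate, pair_losses = pair_losses, grid = grid,
       unpack = unpack)
}

#' Train the data-driven 4f magnifier
#'
#' Convenience wrapper running [optimize_setup()] on a [magnifier_task()]:
#' per step one batch of pairs is simulated, the batch-mean MSE drives one
#' shared AdamW update of the masks and distances.
#'
#' @param task A [magnifier_task()].
#' @param cfg An [optimizer_config()].
#' @return A `discovery_run`.
#' @export
train_magnifier <- function(task, cfg = optimizer_config()) {
  optimize_setup(task$objective, task$init_fn(cfg$seed), cfg,
                 init_fn = task$init_fn)
}
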