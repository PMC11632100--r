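# The optimization engine closing the simulator <-> optimizer loop:
# AdamW updates on the flat parameter vector, random restarts, convergence
# detection, gradient checking, and resumable runs.

#' Optimizer configuration
#'
#' Defaults: AdamW with learning rate `1e-2` for scalar families and `1e-1`
#' for phase rasters (two parameter groups), a 1000-step budget, 5 random
#' restarts, and early stopping when the relative change of the best loss
#' over a 50-step window falls below `1e-5`. Distances are optimized through
#' a softplus re-parameterization (kept positive) and beam-splitter ratios
#' through a logistic one (kept in `(0, 1)`); both are invisible at the
#' interface, which always speaks physical units.
#'
#' @param algorithm `"adamw"` or `"adam"` (AdamW with zero weight decay).
#' @param lr Learning rate for scalar parameter families.
#' @param lr_masks Learning rate for SLM phase rasters.
#' @param steps Step budget per restart.
#' @param restarts Number of random restarts; the best final loss wins.
#' @param window,tol Convergence window (steps) and relative tolerance.
#' @param weight_decay AdamW decoupled weight decay (0 disables).
#' @param seed Integer seed; every random draw of the run derives from it.
#' @return An `ol_optimizer_config`.
#' @export
optimizer_config <- function(algorithm = c("adamw", "adam"), lr = 1e-2,
                             lr_masks = 1e-1, steps = 1000, restarts = 5,
                             window = 50, tol = 1e-5, weight_decay = 0,
                             seed = 1L) {
  algorithm <- match.arg(algorithm)
  stopifnot(lr > 0, lr_masks > 0, steps >= 0, restarts >= 1, window >= 1,
            tol >= 0, weight_decay >= 0)
  structure(list(algorithm = algorithm, lr = lr, lr_masks = lr_masks,
                 steps = as.integer(steps), restarts = as.integer(restarts),
                 window = as.integer(window), tol = tol,
                 weight_decay = weight_decay, seed = as.integer(seed)),
            class = "ol_optimizer_config")
}

# per-coordinate transform codes derived from the packing index:
# 0 identity, 1 softplus (distances), 2 logistic (splitter ratios)
transform_codes <- function(theta) {
  segs <- attr(theta, "index")
  code <- integer(length(theta))
  if (is.null(segs)) return(code)
  for (s in segs) {
    tcode <- if (s$family %in% c("z1", "z2")) 1L
             else if (s$family == "bs") 2L else 0L
    if (tcode != 0L) code[s$offset + seq_len(s$len)] <- tcode
  }
  code
}

softplus <- function(u) ifelse(u > 0, u + log1p(exp(-u)), log1p(exp(u)))
softplus_inv <- function(z) ifelse(z > 30, z, log(expm1(pmax(z, 1e-12))))

to_raw <- function(theta, code) {
  u <- as.numeric(theta)
  u[code == 1L] <- softplus_inv(u[code == 1L])
  u[code == 2L] <- stats::qlogis(pmin(pmax(u[code == 2L], 1e-6), 1 - 1e-6))
  u
}

from_raw <- function(u, code, proto) {
  th <- u
  th[code == 1L] <- softplus(u[code == 1L])
  th[code == 2L] <- stats::plogis(u[code == 2L])
  attributes(th) <- attributes(proto)
  th
}

raw_chain <- function(u, code) {
  d <- rep(1, length(u))
  d[code == 1L] <- stats::plogis(u[code == 1L])
  p <- stats::plogis(u[code == 2L])
  d[code == 2L] <- p * (1 - p)
  d
}

# per-coordinate learning rates: rasters get cfg$lr_masks
lr_vector <- function(theta, cfg) {
  segs <- attr(theta, "index")
  lr <- rep(cfg$lr, length(theta))
  if (!is.null(segs)) {
    for (s in segs)
      if (s$family %in% c("slm_h", "slm_v"))
        lr[s$offset + seq_len(s$len)] <- cfg$lr_masks
  }
  lr
}

#' Optimize a differentiable optical objective
#'
#' Runs AdamW on `loss_fn` from `init` and from `restarts - 1` additional
#' random initializations drawn by `init_fn`, and returns the best restart.
#' `loss_fn(theta)` must return `list(value = <scalar>, grad = <vector>)`
#' (an optional `info` entry, e.g. the arg-min detector, is recorded in the
#' trace). The run is deterministic given `cfg$seed`; a non-finite loss or
#' gradient aborts the restart with a diagnostic and the remaining restarts
#' continue.
#'
#' @param loss_fn Differentiable objective (see Details).
#' @param init Initial parameter vector (with its packing index attribute
#'   when produced by an ansatz; plain numeric vectors work too).
#' @param cfg An [optimizer_config()].
#' @param init_fn Optional `function(seed)` returning a random initial
#'   vector for restarts 2..R; when `NULL`, restarts perturb `init` with
#'   standard normal noise scaled by `0.1 * lr`.
#' @return An object of class `discovery_run`; see [coef.discovery_run()],
#'   [plot.discovery_run()], [resume()].
#' @export
optimize_setup <- function(loss_fn, init, cfg = optimizer_config(), init_fn = NULL) {
  code <- transform_codes(init)
  lr <- lr_vector(init, cfg)
  wd <- if (cfg$algorithm == "adamw") cfg$weight_decay else 0
  if (cfg$steps == 0L) {
    return(structure(list(
      best_value = NA_real_, best_restart = 1L, par = init,
      traces = list(numeric(0)), info = NULL,
      state = list(u = to_raw(init, code), m = numeric(length(init)),
                   v = numeric(length(init)), t = 0L, seed = cfg$seed),
      cfg = cfg, loss_fn = loss_fn, code = code, lr = lr
    ), class = "discovery_run"))
  }
  restarts <- list()
  for (r in seq_len(cfg$restarts)) {
    rs <- cfg$seed + 7919L * (r - 1L)
    theta0 <- if (r == 1L) init
              else if (!is.null(init_fn)) init_fn(rs)
              else perturb_init(init, rs, 0.1 * lr)
    restarts[[r]] <- adamw_run(loss_fn, theta0, cfg, code, lr, wd, rs)
  }
  finite <- vapply(restarts, function(x) is.finite(x$best_value), logical(1))
  if (!any(finite)) stop("all restarts diverged to non-finite losses")
  finals <- vapply(restarts, function(x) x$best_value, numeric(1))
  best <- which.min(finals)
  structure(list(
    best_value = finals[best], best_restart = best,
    par = restarts[[best]]$best_theta,
    traces = lapply(restarts, function(x) x$trace),
    info = restarts[[best]]$info,
    state = restarts[[best]]$state,
    cfg = cfg, loss_fn = loss_fn, code = code, lr = lr
  ), class = "discovery_run")
}

perturb_init <- function(init, seed, scale) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  out <- init + stats::rnorm(length(init)) * scale
  attributes(out) <- attributes(init)
  out
}

adamw_run <- function(loss_fn, theta0, cfg, code, lr, wd, seed,
                      state = NULL) {
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  u <- if (is.null(state)) to_raw(theta0, code) else state$u
  m <- if (is.null(state)) numeric(length(u)) else state$m
  v <- if (is.null(state)) numeric(length(u)) else state$v
  t0 <- if (is.null(state)) 0L else state$t
  trace <- numeric(0); info <- NULL
  best_value <- Inf; best_theta <- theta0
  for (t in seq_len(cfg$steps)) {
    theta <- from_raw(u, code, theta0)
    res <- tryCatch(loss_fn(theta), error = function(e) e)
    if (inherits(res, "condition") || !is.finite(res$value) ||
        any(!is.finite(res$grad))) {
      msg <- if (inherits(res, "condition")) conditionMessage(res)
             else "non-finite loss or gradient"
      warning(sprintf("restart aborted at step %d: %s", t + t0, msg),
              call. = FALSE)
      break
    }
    trace <- c(trace, res$value)
    if (res$value < best_value) {
      best_value <- res$value; best_theta <- theta; info <- res$info
    }
    g <- res$grad * raw_chain(u, code)
    tt <- t + t0
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    mhat <- m / (1 - b1^tt); vhat <- v / (1 - b2^tt)
    u <- u - lr * (mhat / (sqrt(vhat) + eps) + wd * u)
    if (length(trace) > cfg$window) {
      w <- trace[(length(trace) - cfg$window):length(trace)]
      if (abs(max(w) - min(w)) < cfg$tol * max(abs(min(w)), 1e-30)) break
    }
  }
  if (cfg$steps == 0L) { best_value <- NA_real_; best_theta <- theta0 }
  list(best_value = best_value, best_theta = best_theta, trace = trace,
       info = info,
       state = list(u = u, m = m, v = v, t = length(trace) + t0, seed = seed))
}

#' @export
print.discovery_run <- function(x, ...) {
  cat(sprintf("<discovery_run> best loss %.6g (restart %d of %d, %d parameters)\n",
              x$best_value, x$best_restart, length(x$traces), length(x$par)))
  invisible(x)
}

#' @export
summary.discovery_run <- function(object, ...) {
  finals <- vapply(object$traces, function(tr)
    if (length(tr)) min(tr) else NA_real_, numeric(1))
  steps <- vapply(object$traces, length, integer(1))
  out <- list(best_value = object$best_value,
              best_restart = object$best_restart,
              restart_losses = finals, restart_steps = steps,
              n_parameters = length(object$par))
  class(out) <- "summary.discovery_run"
  out
}

#' @export
print.summary.discovery_run <- function(x, ...) {
  cat(sprintf("Discovery run over %d parameters\n", x$n_parameters))
  cat(sprintf("  best loss: %.6g (restart %d)\n", x$best_value, x$best_restart))
  cat("  per-restart best losses:",
      paste(sprintf("%.4g", x$restart_losses), collapse = ", "), "\n")
  cat("  per-restart steps:", paste(x$restart_steps, collapse = ", "), "\n")
  invisible(x)
}

#' Best parameter vector of a discovery run
#'
#' @param object A `discovery_run`.
#' @param ... Ignored.
#' @return The flat parameter vector (physical units) of the best restart.
#' @export
coef.discovery_run <- function(object, ...) object$par

#' Loss-trace plot of a discovery run
#'
#' @param x A `discovery_run`.
#' @param log Use a logarithmic loss axis (default `TRUE`).
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.discovery_run <- function(x, log = TRUE, ...) {
  n <- max(vapply(x$traces, length, integer(1)))
  m <- sapply(x$traces, function(tr) c(tr, rep(NA, n - length(tr))))
  graphics::matplot(m, type = "l", lty = 1, xlab = "step", ylab = "loss",
                    log = if (log) "y" else "", ...)
  invisible(x)
}

#' Resume an optimization from its checkpoint
#'
#' Continues the best restart's AdamW state for `extra_steps` more steps;
#' the continued trace extends the original exactly (same moments, same
#' step count).
#'
#' @param run A `discovery_run`.
#' @param extra_steps Additional step budget.
#' @return An updated `discovery_run`.
#' @export
resume <- function(run, extra_steps) {
  stopifnot(inherits(run, "discovery_run"))
  cfg <- run$cfg
  cfg$steps <- as.integer(extra_steps)
  cfg$window <- .Machine$integer.max %/% 2L  # no early stop on short resumes
  res <- adamw_run(run$loss_fn, run$par, cfg, run$code, run$lr,
                   if (cfg$algorithm == "adamw") cfg$weight_decay else 0,
                   run$state$seed, state = run$state)
  run$traces[[run$best_restart]] <- c(run$traces[[run$best_restart]], res$trace)
  if (is.finite(res$best_value) && res$best_value < run$best_value) {
    run$best_value <- res$best_value
    run$par <- res$best_theta
    run$info <- res$info
  }
  run$state <- res$state
  run
}

#' Compare analytic gradients with central finite differences
#'
#' Probes randomly chosen coordinates (covering every parameter family when
#' the vector carries a packing index) and returns the worst relative
#' disagreement between the adjoint gradient and a central finite
#' difference. Coordinates whose analytic and numerical gradients are both
#' tiny compared to the gradient norm are compared absolutely.
#'
#' @param loss_fn Objective as in [optimize_setup()].
#' @param params Parameter vector at which to check.
#' @param n_probes Number of probed coordinates (>= 1).
#' @param h Relative step size for the finite difference.
#' @param seed Seed for the probe choice.
#' @return Maximum relative error over the probes.
#' @export
grad_check <- function(loss_fn, params, n_probes = 10, h = 1e-5, seed = 1L) {
  stopifnot(n_probes >= 1)
  res <- loss_fn(params)
  g <- res$grad
  segs <- attr(params, "index")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  coords <- integer(0)
  if (!is.null(segs)) {
    fams <- unique(vapply(segs, function(s) s$family, character(1)))
    for (f in fams) {
      pool <- unlist(lapply(segs[vapply(segs, function(s) s$family == f, logical(1))],
                            function(s) s$offset + seq_len(s$len)))
      coords <- c(coords, sample(pool, min(length(pool), max(1L, n_probes %/% length(fams)))))
    }
  }
  if (length(coords) < n_probes)
    coords <- unique(c(coords, sample(length(params),
                                      min(length(params), n_probes))))
  gnorm <- max(abs(g), 1e-300)
  worst <- 0
  for (i in coords) {
    step <- h * max(1, abs(params[i]))
    tp <- params; tp[i] <- tp[i] + step
    tm <- params; tm[i] <- tm[i] - step
    fd <- (loss_fn(tp)$value - loss_fn(tm)$value) / (2 * step)
    denom <- max(abs(fd), abs(g[i]))
    err <- if (denom < 1e-8 * gnorm) abs(g[i] - fd) / gnorm
           else abs(g[i] - fd) / denom
    worst <- max(worst, err)
  }
  worst
}
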