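# Detector statistics and loss functions: the intensity-density loss, smooth
# minimum aggregation over detectors, the data-driven MSE loss and the
# Beer-Lambert model of stimulated emission depletion.

#' Detector readout from a field
#'
#' Converts a focused field into the per-pixel detected intensity raster for
#' one of the standard observables: the transverse intensity
#' `|Ex|^2 + |Ey|^2`, the longitudinal intensity `|Ez|^2`, or the total.
#'
#' @param field An `ol_vector_field` (or `ol_scalar_field`, total only).
#' @param component `"total"`, `"transverse"` or `"longitudinal"`.
#' @return An `ol_detector_readout`: list with `i_det` (numeric matrix),
#'   `i_max`, `component` and `grid`.
#' @export
detect <- function(field, component = c("total", "transverse", "longitudinal")) {
  component <- match.arg(component)
  i_det <- field_intensity(field, component)
  structure(list(i_det = i_det, i_max = max(i_det), component = component,
                 grid = field$grid),
            class = "ol_detector_readout")
}

as_readout <- function(x, grid = NULL) {
  if (inherits(x, "ol_detector_readout")) return(x)
  if (!is.matrix(x)) stop("expected a detector readout or an intensity matrix")
  structure(list(i_det = x, i_max = max(x), component = "total", grid = grid),
            class = "ol_detector_readout")
}

#' Loss configuration for the density loss
#'
#' @param epsilon Threshold fraction in `[0, 1]`: pixels enter the loss when
#'   their intensity strictly exceeds `epsilon * i_max`.
#' @param beta Soft-min sharpness for detector aggregation (`> 0`).
#' @param soft_threshold If `TRUE`, the hard pixel selection is replaced by a
#'   sigmoid of temperature `soft_temp` (a smoother variant of the same
#'   objective).
#' @param soft_temp Sigmoid temperature as a fraction of `i_max`.
#' @return An `ol_loss_config`.
#' @export
loss_config <- function(epsilon = 0.5, beta = 100, soft_threshold = FALSE,
                        soft_temp = 0.02) {
  stopifnot(epsilon >= 0, epsilon <= 1, beta > 0, soft_temp > 0)
  structure(list(epsilon = epsilon, beta = beta,
                 soft_threshold = soft_threshold, soft_temp = soft_temp),
            class = "ol_loss_config")
}

# threshold statistics shared by the loss and its gradient
density_stats <- function(i_det, cfg) {
  i_max <- max(i_det)
  if (i_max <= 0) stop("no signal above threshold: detector raster is all zero")
  thr <- cfg$epsilon * i_max
  if (isTRUE(cfg$soft_threshold)) {
    w <- stats::plogis((i_det - thr) / (cfg$soft_temp * i_max))
    i_eps <- i_det * w
    area <- sum(w)
  } else {
    keep <- i_det > thr
    i_eps <- i_det * keep
    area <- sum(keep)
  }
  I_eps <- sum(i_eps)
  if (I_eps <= 0) stop("no signal above threshold")
  list(i_max = i_max, thr = thr, keep = i_eps > 0, area = area, I_eps = I_eps)
}

#' Inverse-density loss over a detector raster
#'
#' The design loss that rewards small, bright spots:
#' pixels strictly above the threshold `epsilon * i_max` are retained
#' (`i_eps`), `I_eps` is their intensity sum, `Area` the count of retained
#' pixels, and the loss is `Area / I_eps` (the inverse of the mean retained
#' intensity density). Minimizing it concentrates the detected light into
#' few, intense pixels.
#'
#' The loss is differentiated through the retained pixel values; the
#' threshold selection and the `Area` factor act as the piecewise-constant
#' scale that adapts the gradient to the current spot extent (see
#' [density_loss_grad()]).
#'
#' @param readout An `ol_detector_readout` (from [detect()]) or a
#'   non-negative intensity matrix.
#' @param cfg An [loss_config()].
#' @return A positive scalar.
#' @examples
#' density_loss(matrix(1, 8, 8))        # uniform raster: 1
#' m <- matrix(0, 8, 8); m[4, 4] <- 10
#' density_loss(m)                      # single bright pixel: 1/10
#' @export
density_loss <- function(readout, cfg = loss_config()) {
  readout <- as_readout(readout)
  if (any(readout$i_det < 0)) stop("intensity raster must be non-negative")
  st <- density_stats(readout$i_det, cfg)
  st$area / st$I_eps
}

#' Gradient of the density loss with respect to the raster
#'
#' Treating the pixel selection and the `Area` factor as locally constant
#' (their derivative is zero almost everywhere), the gradient is
#' `-Area / I_eps^2` on retained pixels and 0 elsewhere.
#'
#' @inheritParams density_loss
#' @return A numeric matrix of the same shape as the raster.
#' @export
density_loss_grad <- function(readout, cfg = loss_config()) {
  readout <- as_readout(readout)
  st <- density_stats(readout$i_det, cfg)
  if (isTRUE(cfg$soft_threshold)) {
    # soft variant: differentiate i_det * w(i_det) with w fixed-point weights
    w <- stats::plogis((readout$i_det - st$thr) / (cfg$soft_temp * st$i_max))
    g <- -st$area / st$I_eps^2 * w
  } else {
    g <- matrix(0, nrow(readout$i_det), ncol(readout$i_det))
    g[st$keep] <- -st$area / st$I_eps^2
  }
  g
}

#' Smooth minimum over per-detector losses
#'
#' The numerically stable log-sum-exp soft minimum
#' `-logsumexp(-beta * losses) / beta`, used to let the detector with the
#' lowest loss drive the parameter update while keeping the objective smooth
#' everywhere. As `beta -> Inf` it converges to `min(losses)`; for any finite
#' `beta`, `min(l) - log(n)/beta <= softmin(l) <= min(l)`.
#'
#' @param losses Numeric vector of per-detector losses (length >= 1).
#' @param beta Sharpness parameter (`> 0`).
#' @return A scalar.
#' @export
softmin <- function(losses, beta = 100) {
  if (length(losses) == 0) stop("'losses' must contain at least one detector")
  stopifnot(beta > 0, all(is.finite(losses)))
  m <- min(losses)
  m - log(sum(exp(-beta * (losses - m)))) / beta
}

#' Soft-min weights (gradient of [softmin()] w.r.t. the losses)
#'
#' @inheritParams softmin
#' @return A probability vector: `exp(-beta*l) / sum(exp(-beta*l))`.
#' @export
softmin_weights <- function(losses, beta = 100) {
  m <- min(losses)
  w <- exp(-beta * (losses - m))
  w / sum(w)
}

#' Mean squared error between two rasters
#'
#' The data-driven imaging loss: the mean of squared pixel differences
#' between the detected intensity pattern and its ground-truth target.
#'
#' @param detected,target Numeric matrices of equal shape.
#' @return A non-negative scalar.
#' @export
mse_loss <- function(detected, target) {
  if (!all(dim(detected) == dim(target))) stop("raster shapes must match")
  mean((detected - target)^2)
}

#' STED parameters for the Beer-Lambert depletion model
#'
#' @param alpha Dimensionless depletion strength (attenuation coefficient).
#' @param emission_wavelength Fluorophore emission wavelength in nanometres
#'   (metadata, not used in the intensity computation).
#' @return An `ol_sted_params`.
#' @export
sted_params <- function(alpha = 10, emission_wavelength = 560) {
  stopifnot(alpha >= 0)
  structure(list(alpha = alpha, emission_wavelength = emission_wavelength),
            class = "ol_sted_params")
}

#' Effective STED beam via Beer-Lambert depletion
#'
#' Models stimulated emission depletion without time-dependent kinetics: the
#' excitation intensity is attenuated exponentially where the depletion beam
#' is bright,
#' `I_eff = I_exc * exp(-alpha * I_dep / max(I_dep))`.
#' With a doughnut-shaped depletion beam this carves away the flanks of the
#' excitation spot and leaves a sub-diffraction effective beam around the
#' doughnut null. Normalizing by `max(I_dep)` makes `alpha` a pure shape
#' parameter. A zero depletion raster returns the excitation unchanged.
#'
#' @param excitation,depletion Non-negative intensity matrices on the same
#'   raster.
#' @param p An [sted_params()].
#' @return The effective intensity matrix.
#' @export
sted_effective <- function(excitation, depletion, p = sted_params()) {
  if (!all(dim(excitation) == dim(depletion))) stop("raster shapes must match")
  if (any(excitation < 0) || any(depletion < 0))
    stop("intensity rasters must be non-negative")
  dmax <- max(depletion)
  if (dmax == 0) return(excitation)
  excitation * exp(-p$alpha * depletion / dmax)
}
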