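# Reproducible presets for the design experiments, at configurable
# resolution: the data-driven 4f magnifier, fixed-mask topology discovery
# (STED doughnut and sharp longitudinal focus), their highly parameterized
# variants, and the two-color hybrid blueprint.

preset_names <- c("magnifier_4f", "sted_topology", "sharp_focus_topology",
                  "sted_parameterized", "sharp_focus_parameterized",
                  "blueprint")

# physical width of the preset grids (micrometres); resolution only changes
# the sampling, not the physics being emulated
PRESET_WIDTH_UM <- 2560

preset_grid <- function(resolution) {
  make_grid(resolution, resolution, PRESET_WIDTH_UM / resolution)
}

# the canonical fixed-mask 3x3 configuration: two beams enter at S1/S2, three
# detectors terminate the N stubs; the four units adjacent to the active
# ports (S1, S2, N1, N2) expose their distances and wave plates, which with
# the nine splitter ratios gives the 25 optimizable scalars of the
# fixed-mask topology search
topology_spec <- function(grid, fixed_elements, sources, n_detectors = 3) {
  dets <- lapply(paste0("N", seq_len(n_detectors)), function(p)
    list(port = p, na = 0.9, nx = 32L, extent = 3, focal = NULL))
  ansatz_spec(3, 3, grid = grid, mode = "fixed_masks",
              sources = sources, detectors = dets,
              fixed_elements = fixed_elements)
}

topology_active <- function(setup) {
  # unit ids: S stubs 1..3, W stubs 4..6, internal 7..18, N stubs 19..21
  units <- c(1L, 2L, 19L, 20L)
  active_params(setup, bs = TRUE, z1 = units, z2 = units, wp = units)
}

#' Configure one of the bundled discovery presets
#'
#' Returns the full configuration of a named experiment preset: the built
#' ansatz (or training task), the active parameter selection, the loss, and
#' the optimizer settings, all scaled to the requested resolution. The
#' presets emulate the canonical design studies:
#' \describe{
#'   \item{magnifier_4f}{data-driven rediscovery of the inverting 2x
#'     magnifier from input/target pairs (two SLM rasters + 3 distances).}
#'   \item{sted_topology}{fixed-mask 3x3 topology search (25 scalars) that
#'     routes a 532 nm depletion beam through a frozen spiral mask and
#'     overlaps it with the 650 nm excitation; loss = inverse density of the
#'     Beer-Lambert effective beam (transverse component).}
#'   \item{sharp_focus_topology}{fixed-mask topology search with a frozen
#'     radial polarization converter; loss on the longitudinal component,
#'     whose tight focus is the sharp-spot observable.}
#'   \item{sted_parameterized / sharp_focus_parameterized}{the same
#'     objectives with three optimizable super-SLMs (full mode).}
#'   \item{blueprint}{two-color (650/532 nm) full-mode search on the total
#'     intensity of the effective beam.}
#' }
#'
#' @param name Preset name (see above).
#' @param resolution Grid pixels per axis (the physical width stays fixed at
#'   2.56 mm, so resolution only refines the sampling).
#' @param steps,restarts Optimizer budget overrides.
#' @param seed Seed controlling initialization and restarts.
#' @return An `ol_preset` list: `name`, `setup`/`task`, `active`,
#'   `objective`, `init`, `init_fn`, `cfg`, and a `report` function.
#' @export
preset_config <- function(name = preset_names, resolution = 64,
                          steps = 200, restarts = 3, seed = 1L) {
  name <- match.arg(name)
  grid <- preset_grid(resolution)
  cfg <- optimizer_config(steps = steps, restarts = restarts, seed = seed)
  if (name == "magnifier_4f") {
    tgrid <- make_grid(max(32, resolution %/% 2), max(32, resolution %/% 2),
                       PRESET_WIDTH_UM / 8 / max(32, resolution %/% 2))
    dataset <- make_4f_dataset(20, 2, tgrid, seed = seed)
    task <- magnifier_task(dataset, tgrid, wavelength = 650, batch = 10,
                           seed = seed)
    return(structure(list(name = name, kind = "data_driven", task = task,
                          grid = tgrid, dataset = dataset, cfg = cfg,
                          objective = task$objective, init = task$init,
                          init_fn = task$init_fn),
                     class = "ol_preset"))
  }

  src_650 <- list(port = "S2", wavelength = 650, polarization = c(1, 0),
                  waist = PRESET_WIDTH_UM / 8)
  src_532 <- list(port = "S1", wavelength = 532, polarization = c(1, 0),
                  waist = PRESET_WIDTH_UM / 8)
  z_range <- c(1e4, 1e5)
  if (name %in% c("sted_topology", "sharp_focus_topology")) {
    if (name == "sted_topology") {
      fixed <- list("1" = list(type = "spiral", charge = 1L))
      sources <- list(src_650, src_532)
      component <- "transverse"
      sted <- list(params = sted_params(alpha = 10), excitation = 650,
                   depletion = 532)
    } else {
      fixed <- list("1" = list(type = "radial"),
                    "2" = list(type = "spiral", charge = 1L))
      sources <- list(list(port = "S1", wavelength = 650,
                           polarization = c(1, 0),
                           waist = PRESET_WIDTH_UM / 8))
      component <- "longitudinal"
      sted <- NULL
    }
    setup <- build_ansatz(topology_spec(grid, fixed, sources))
    active <- topology_active(setup)
  } else {
    sources <- if (name == "sharp_focus_parameterized")
      list(list(port = "S1", wavelength = 650, polarization = c(1, 0),
                waist = PRESET_WIDTH_UM / 8))
    else list(src_650, src_532)
    component <- switch(name,
      sted_parameterized = "transverse",
      sharp_focus_parameterized = "longitudinal",
      blueprint = "total")
    sted <- if (name %in% c("sted_parameterized", "blueprint"))
      list(params = sted_params(alpha = 10), excitation = 650,
           depletion = 532) else NULL
    dets <- lapply(paste0("N", 1:3), function(p)
      list(port = p, na = 0.9, nx = 32L, extent = 3, focal = NULL))
    setup <- build_ansatz(ansatz_spec(3, 3, grid = grid, mode = "full",
                                      sources = sources, detectors = dets))
    slm_units <- c(1L, 2L, 19L)
    zu <- c(1L, 2L, 19L, 20L)
    active <- active_params(setup, bs = TRUE, z1 = zu, z2 = zu,
                            wp = slm_units, slm = slm_units)
  }
  objective <- ansatz_objective(setup, active, loss_config(epsilon = 0.5),
                                component = component, sted = sted)
  init_fn <- ansatz_init_fn(setup, active, z_range = z_range, z_default = 3e4)
  structure(list(name = name, kind = "ansatz", setup = setup, active = active,
                 component = component, sted = sted, grid = grid, cfg = cfg,
                 objective = objective, init = init_fn(seed),
                 init_fn = init_fn),
            class = "ol_preset")
}

#' Run a discovery preset end to end
#'
#' Builds the preset, runs the optimization, and assembles the report:
#' best loss, the discovered topology (ansatz presets), and the headline
#' beam observables (per-axis FWHM, spot size phi, on-axis intensities).
#' With `out_dir` set, the loss trace (CSV), topology (JSON) and mask
#' previews (PNG) are written there.
#'
#' @param preset An `ol_preset` from [preset_config()], or a preset name.
#' @param out_dir Optional output directory for artifacts.
#' @param ... Passed to [preset_config()] when `preset` is a name.
#' @return List with the `discovery_run`, the `report`, and the preset.
#' @export
run_preset <- function(preset, out_dir = NULL, ...) {
  if (is.character(preset)) preset <- preset_config(preset, ...)
  stopifnot(inherits(preset, "ol_preset"))
  run <- optimize_setup(preset$objective, preset$init, preset$cfg,
                        init_fn = preset$init_fn)
  report <- if (preset$kind == "data_driven")
    report_magnifier(preset, run) else report_ansatz(preset, run)
  if (!is.null(out_dir)) write_preset_artifacts(preset, run, report, out_dir)
  list(run = run, report = report, preset = preset)
}

report_magnifier <- function(preset, run) {
  grid <- preset$grid
  tri <- make_mask(grid, "triangle", size_fraction = 0.35)
  held_out <- list(list(input = tri, target = imaging_map(tri^2, grid, 2)))
  final <- preset$task$pair_losses(coef(run), held_out)
  init_mse <- preset$task$pair_losses(preset$init, held_out)
  I <- preset$task$simulate(coef(run), tri)
  est <- estimate_magnification(tri^2, I, grid)
  list(kind = "magnifier", best_loss = run$best_value,
       heldout_mse = final, heldout_mse_init = init_mse,
       magnification = est$magnification, inverted = est$inverted)
}

report_ansatz <- function(preset, run) {
  params <- unpack_params(coef(run), ansatz_params(preset$setup), preset$setup)
  fwd <- forward_ansatz(preset$setup, params)
  port <- run$info$detector %||% names(fwd$detectors)[1]
  det <- fwd$detectors[[port]]
  out <- list(kind = "ansatz", best_loss = run$best_value, detector = port,
              topology = extract_topology(preset$setup, params, 0.01))
  if (!is.null(preset$sted)) {
    exc <- det$groups[[as.character(preset$sted$excitation)]]
    dep <- det$groups[[as.character(preset$sted$depletion)]]
    comp_int <- function(g) {
      if (is.null(g)) return(NULL)
      switch(preset$component,
        transverse = Mod(g$ex)^2 + Mod(g$ey)^2,
        total = Mod(g$ex)^2 + Mod(g$ey)^2 + Mod(g$ez)^2,
        longitudinal = Mod(g$ez)^2)
    }
    I_exc <- comp_int(exc); I_dep <- comp_int(dep)
    if (!is.null(I_exc)) {
      eff <- if (is.null(I_dep)) I_exc
             else sted_effective(I_exc, I_dep, preset$sted$params)
      out$excitation <- safe_spot(I_exc, det$grid)
      out$depletion <- if (!is.null(I_dep)) safe_spot(I_dep, det$grid) else NULL
      out$effective <- safe_spot(eff, det$grid)
      out$rasters <- list(excitation = I_exc, depletion = I_dep,
                          effective = eff)
    }
  } else {
    I_long <- detector_intensity(det, "longitudinal")
    I_trans <- detector_intensity(det, "transverse")
    if (!is.null(I_long)) {
      out$longitudinal <- safe_spot(I_long, det$grid)
      ctr <- c(which.min(abs(det$grid$y)), which.min(abs(det$grid$x)))
      out$on_axis_longitudinal <- I_long[ctr[1], ctr[2]]
      out$on_axis_transverse <- I_trans[ctr[1], ctr[2]]
      out$rasters <- list(longitudinal = I_long, transverse = I_trans)
    }
  }
  out
}

safe_spot <- function(I, grid) {
  tryCatch(spot_metrics(I, grid), error = function(e) NULL)
}

write_preset_artifacts <- function(preset, run, report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tr <- run$traces[[run$best_restart]]
  utils::write.csv(data.frame(step = seq_along(tr), loss = tr),
                   file.path(out_dir, "loss_trace.csv"), row.names = FALSE)
  if (!is.null(report$topology))
    topology_json(report$topology, file.path(out_dir, "topology.json"))
  if (!is.null(report$rasters)) {
    for (nm in names(report$rasters)) {
      r <- report$rasters[[nm]]
      if (!is.null(r))
        write_intensity_png(r, file.path(out_dir, paste0(nm, ".png")))
    }
  }
  manifest <- list(preset = preset$name, best_loss = run$best_value,
                   n_parameters = length(coef(run)),
                   restarts = length(run$traces), seed = preset$cfg$seed)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             file.path(out_dir, "manifest.json"))
  invisible()
}
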