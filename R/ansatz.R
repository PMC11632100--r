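# The continuous grid ansatz: a lattice of tunable beam splitters whose
# internal edges and external stubs each host one "building unit" (a
# polarization-resolved super-SLM, a propagation distance z1, a wave plate,
# and a second distance z2). Setting splitter ratios to their extremes turns
# optical paths on and off, so discrete topology search becomes smooth
# optimization over the continuous parameter set.

#' Specify a grid ansatz
#'
#' A `rows x cols` lattice of beam-splitter nodes. Light flows upward and
#' rightward: node `(i, j)` takes inputs from the south and west and sends
#' outputs north and east. Every internal edge and every external stub hosts
#' one building unit (super-SLM, distance `z1`, wave plate, distance `z2`).
#' Sources feed the lower/left stubs and detectors terminate the upper/right
#' stubs, which uniquely reproduces the canonical 3 x 3 element audit:
#' 9 splitters, 24 units (24 super-SLMs = 48 SLM panels, 24 wave plates),
#' 6 source and 6 detector ports.
#'
#' @param rows,cols Lattice dimensions (>= 1).
#' @param grid The computational `ol_grid` shared by all elements.
#' @param mode `"full"` (SLM rasters optimizable) or `"fixed_masks"`
#'   (rasters frozen to the patterns in `fixed_elements`).
#' @param sources List of source descriptors
#'   `list(port =, wavelength =, polarization =, waist =)`. Ports are
#'   `"S1".."S<cols>"` (south stubs) and `"W1".."W<rows>"` (west stubs).
#'   Default: all input stubs, wavelength triple 625/530/470 nm, x-polarized.
#' @param detectors List of detector descriptors
#'   `list(port =, na =, nx =, extent =, focal =)`. Ports are
#'   `"N1".."N<cols>"` and `"E1".."E<rows>"`. Each detector is a high-NA
#'   objective focusing onto an `nx x nx` camera window of half-width
#'   `extent` micrometres. Default: all output stubs, NA 0.9.
#' @param fixed_elements Named list (names are unit ids as characters) of
#'   fixed elements for `fixed_masks` mode: `list(type = "spiral", charge =)`,
#'   `list(type = "lens", focal =)`, `list(type = "radial")` (polarization
#'   converter) or `list(type = "mask", h =, v =)` with phase matrices.
#' @return An `ol_ansatz_spec`.
#' @export
ansatz_spec <- function(rows = 3, cols = 3, grid = make_grid(64, 64, 40),
                        mode = c("full", "fixed_masks"),
                        sources = NULL, detectors = NULL,
                        fixed_elements = list()) {
  mode <- match.arg(mode)
  rows <- as.integer(rows); cols <- as.integer(cols)
  stopifnot(rows >= 1L, cols >= 1L, inherits(grid, "ol_grid"))
  in_ports <- c(paste0("S", seq_len(cols)), paste0("W", seq_len(rows)))
  out_ports <- c(paste0("N", seq_len(cols)), paste0("E", seq_len(rows)))
  if (is.null(sources)) {
    wl <- rep(c(625, 530, 470), length.out = length(in_ports))
    sources <- lapply(seq_along(in_ports), function(i)
      list(port = in_ports[i], wavelength = wl[i], polarization = c(1, 0),
           waist = NULL))
  }
  if (is.null(detectors)) {
    detectors <- lapply(out_ports, function(p)
      list(port = p, na = 0.9, nx = 32L, extent = 3, focal = NULL))
  }
  sp <- vapply(sources, function(s) s$port, character(1))
  dp <- vapply(detectors, function(d) d$port, character(1))
  if (anyDuplicated(sp) || !all(sp %in% in_ports))
    stop("source ports must be distinct input stubs (S*/W*)")
  if (anyDuplicated(dp) || !all(dp %in% out_ports))
    stop("detector ports must be distinct output stubs (N*/E*)")
  if (length(sources) > length(in_ports) || length(detectors) > length(out_ports))
    stop("more sources/detectors than external ports")
  structure(list(rows = rows, cols = cols, grid = grid, mode = mode,
                 sources = sources, detectors = detectors,
                 fixed_elements = fixed_elements),
            class = "ol_ansatz_spec")
}

node_index <- function(spec, i, j) (i - 1L) * spec$cols + j

#' Build (wire) a grid ansatz
#'
#' Enumerates the nodes, edges and building units of an [ansatz_spec()] in a
#' deterministic order and computes the element audit. Unit ids are assigned
#' source stubs first (S then W), then internal edges (vertical, then
#' horizontal, row-major), then detector stubs (N then E).
#'
#' @param spec An `ol_ansatz_spec`.
#' @return An `ol_ansatz` setup: the input specification plus `edges` (one
#'   building unit each) and `audit` (element counts).
#' @examples
#' a <- build_ansatz(ansatz_spec(3, 3))
#' a$audit$slm_panels  # 48
#' @export
build_ansatz <- function(spec) {
  stopifnot(inherits(spec, "ol_ansatz_spec"))
  r <- spec$rows; cc <- spec$cols
  edges <- list()
  add_edge <- function(kind, from, to) {
    edges[[length(edges) + 1L]] <<- list(uid = length(edges) + 1L, kind = kind,
                                         from = from, to = to)
  }
  for (j in seq_len(cc))
    add_edge("src", list(type = "port", port = paste0("S", j)),
             list(type = "node", node = node_index(spec, 1L, j), side = "S"))
  for (i in seq_len(r))
    add_edge("src", list(type = "port", port = paste0("W", i)),
             list(type = "node", node = node_index(spec, i, 1L), side = "W"))
  for (i in seq_len(r - 1L)) for (j in seq_len(cc))
    add_edge("int", list(type = "node", node = node_index(spec, i, j), side = "N"),
             list(type = "node", node = node_index(spec, i + 1L, j), side = "S"))
  for (i in seq_len(r)) for (j in seq_len(cc - 1L))
    add_edge("int", list(type = "node", node = node_index(spec, i, j), side = "E"),
             list(type = "node", node = node_index(spec, i, j + 1L), side = "W"))
  for (j in seq_len(cc))
    add_edge("det", list(type = "node", node = node_index(spec, r, j), side = "N"),
             list(type = "port", port = paste0("N", j)))
  for (i in seq_len(r))
    add_edge("det", list(type = "node", node = node_index(spec, i, cc), side = "E"),
             list(type = "port", port = paste0("E", i)))
  n_units <- length(edges)
  internal <- r * (cc - 1L) + cc * (r - 1L)
  audit <- list(
    bs = r * cc,
    internal_edges = internal,
    external_stubs = 2L * (r + cc),
    units = n_units,
    sslm = n_units,
    slm_panels = 2L * n_units,
    wave_plates = n_units,
    source_ports = r + cc,
    detector_ports = r + cc,
    sources = length(spec$sources),
    detectors = length(spec$detectors)
  )
  stopifnot(n_units == internal + 2L * (r + cc))
  structure(c(spec, list(edges = edges, audit = audit)), class = "ol_ansatz")
}

#' @export
print.ol_ansatz <- function(x, ...) {
  a <- x$audit
  cat(sprintf(paste0("<ol_ansatz> %d x %d lattice: %d beam splitters, ",
                     "%d building units (%d SLM panels, %d wave plates), ",
                     "%d sources, %d detectors; mode '%s'\n"),
              x$rows, x$cols, a$bs, a$units, a$slm_panels, a$wave_plates,
              a$sources, a$detectors, x$mode))
  invisible(x)
}

# default structured parameter set of a built ansatz
#' Default parameter set of a grid ansatz
#'
#' Beam splitters balanced (T = 0.5), distances `z1 = z2 = 5` cm, wave
#' plates at zero retardance, SLM rasters flat (full mode).
#'
#' @param setup An `ol_ansatz` from [build_ansatz()].
#' @param z_default Default propagation distance in micrometres.
#' @return A structured parameter list (`bs`, `z1`, `z2`, `wp_eta`,
#'   `wp_theta`, and per-unit `slm_h`/`slm_v` rasters in full mode).
#' @export
ansatz_params <- function(setup, z_default = 5e4) {
  n_units <- setup$audit$units
  p <- list(
    bs = rep(0.5, setup$audit$bs),
    z1 = rep(z_default, n_units),
    z2 = rep(z_default, n_units),
    wp_eta = rep(0, n_units),
    wp_theta = rep(0, n_units)
  )
  if (setup$mode == "full") {
    zmat <- matrix(0, setup$grid$ny, setup$grid$nx)
    p$slm_h <- rep(list(zmat), n_units)
    p$slm_v <- rep(list(zmat), n_units)
  }
  p
}

# ---- active parameter selection, packing ------------------------------------

#' Select the optimizable parameter families of an ansatz
#'
#' @param setup An `ol_ansatz`.
#' @param bs `TRUE` (all nodes), `FALSE`, or node indices.
#' @param z1,z2 Unit indices whose distances are optimizable (or `TRUE` for
#'   all, `FALSE` for none).
#' @param wp Unit indices whose wave-plate angles (eta and theta) are
#'   optimizable.
#' @param slm Unit indices whose super-SLM rasters (both panels) are
#'   optimizable (full mode only).
#' @return An `ol_active` selection.
#' @export
active_params <- function(setup, bs = TRUE, z1 = FALSE, z2 = FALSE,
                          wp = FALSE, slm = FALSE) {
  idx <- function(sel, n) {
    if (isTRUE(sel)) seq_len(n)
    else if (identical(sel, FALSE)) integer(0)
    else as.integer(sel)
  }
  n_units <- setup$audit$units
  a <- list(bs = idx(bs, setup$audit$bs),
            z1 = idx(z1, n_units), z2 = idx(z2, n_units),
            wp = idx(wp, n_units), slm = idx(slm, n_units))
  if (length(a$slm) > 0 && setup$mode != "full")
    stop("SLM rasters are frozen constants in fixed_masks mode")
  structure(a, class = "ol_active")
}

#' Count the scalar degrees of freedom of an ansatz configuration
#'
#' The exact integer count of optimizable scalars selected by an
#' [active_params()] choice: one per beam-splitter ratio, one per active
#' distance, two per active wave plate (retardance and orientation), and
#' `2 * nx * ny` per active super-SLM (two phase rasters).
#'
#' @param setup An `ol_ansatz`.
#' @param active An `ol_active` selection.
#' @return An integer (double when the count exceeds `.Machine$integer.max`).
#' @export
count_parameters <- function(setup, active) {
  stopifnot(inherits(setup, "ol_ansatz"), inherits(active, "ol_active"))
  npx <- as.numeric(setup$grid$nx) * setup$grid$ny
  length(active$bs) + length(active$z1) + length(active$z2) +
    2 * length(active$wp) + 2 * npx * length(active$slm)
}

# flat packing of the active coordinates; returns the vector with an index
# map attribute so pack/unpack round-trip exactly
pack_params <- function(params, setup, active) {
  segs <- list(); vec <- numeric(0)
  push <- function(family, idx, values) {
    segs[[length(segs) + 1L]] <<- list(family = family, idx = idx,
                                       offset = length(vec), len = length(values))
    vec <<- c(vec, as.numeric(values))
  }
  for (i in active$bs) push("bs", i, params$bs[i])
  for (i in active$z1) push("z1", i, params$z1[i])
  for (i in active$z2) push("z2", i, params$z2[i])
  for (i in active$wp) {
    push("wp_eta", i, params$wp_eta[i])
    push("wp_theta", i, params$wp_theta[i])
  }
  for (i in active$slm) {
    push("slm_h", i, params$slm_h[[i]])
    push("slm_v", i, params$slm_v[[i]])
  }
  attr(vec, "index") <- segs
  vec
}

unpack_params <- function(vec, params, setup) {
  segs <- attr(vec, "index")
  if (is.null(segs)) stop("flat vector lacks its packing index")
  for (s in segs) {
    vals <- vec[s$offset + seq_len(s$len)]
    if (s$family %in% c("slm_h", "slm_v")) {
      params[[s$family]][[s$idx]] <- matrix(vals, setup$grid$ny, setup$grid$nx)
    } else {
      params[[s$family]][s$idx] <- vals
    }
  }
  params
}

# gradient list (named per engine parameter) -> flat vector aligned with vec
pack_grad <- function(pgrad, vec, setup) {
  segs <- attr(vec, "index")
  out <- numeric(length(vec))
  for (s in segs) {
    nm <- paste0(s$family, "_", s$idx)
    g <- pgrad[[nm]]
    if (!is.null(g)) out[s$offset + seq_len(s$len)] <- as.numeric(g)
  }
  out
}

param_name <- function(family, idx) paste0(family, "_", idx)

# ---- forward evaluation -----------------------------------------------------

ansatz_source_field <- function(setup, src) {
  gaussian_source(setup$grid, src$wavelength,
                  waist = src$waist %||% NULL,
                  polarization = src$polarization %||% c(1, 0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

detector_geometry <- function(setup, det, wavelength) {
  half <- min(setup$grid$nx * setup$grid$pitch[1],
              setup$grid$ny * setup$grid$pitch[2]) / 2
  focal <- det$focal %||% (0.95 * half / det$na)
  window <- output_window(det$nx, det$nx, det$extent, det$extent)
  fp <- focus_prep(setup$grid, wavelength, det$na, focal)
  list(fp = fp, window = window)
}

# evaluate one building unit on a tracked pair; returns the transformed pair
ansatz_unit <- function(tape, v, setup, params, active, uid, wavelength, noise) {
  if (is.null(v)) return(NULL)
  grid <- setup$grid
  # super-SLM (or fixed element)
  if (setup$mode == "full") {
    opt <- uid %in% active$slm
    for (panel in c("slm_h", "slm_v")) {
      mask <- params[[panel]][[uid]]
      tr <- if (noise_is_null(noise)) NULL
            else mask_transmission(mask, grid, noise,
                                   salt = uid * 2L + (panel == "slm_v"))
      comp <- if (panel == "slm_h") "ex" else "ey"
      v[[comp]] <- tp_phase(tape, v[[comp]],
                            phase = if (is.null(tr)) mask else NULL,
                            pname = if (opt) param_name(panel, uid) else NULL,
                            tr = tr)
    }
  } else {
    fe <- setup$fixed_elements[[as.character(uid)]]
    if (!is.null(fe)) v <- apply_fixed_element(tape, v, setup, fe, wavelength, noise)
  }
  # z1 hop
  v <- unit_prop(tape, v, setup, params, active, uid, "z1", wavelength)
  # wave plate
  eta <- params$wp_eta[uid]; theta <- params$wp_theta[uid]
  if (!noise_is_null(noise) && noise$phase_noise > 0)
    eta <- eta + noise_draw(noise, 1, salt = 97L + uid) * noise$phase_noise
  opt_wp <- uid %in% active$wp
  v <- tp_jones(tape, v$ex, v$ey, eta, theta,
                eta_name = if (opt_wp) param_name("wp_eta", uid) else NULL,
                theta_name = if (opt_wp) param_name("wp_theta", uid) else NULL)
  # z2 hop
  unit_prop(tape, v, setup, params, active, uid, "z2", wavelength)
}

unit_prop <- function(tape, v, setup, params, active, uid, family, wavelength) {
  z <- params[[family]][uid]
  if (z == 0) return(v)
  opt <- uid %in% active[[family]]
  prep <- rs_prep(setup$grid, wavelength, z, if (opt) c("z", "dz") else "z")
  zname <- if (opt) param_name(family, uid) else NULL
  list(ex = tp_prop(tape, v$ex, prep, zname),
       ey = tp_prop(tape, v$ey, prep, zname))
}

apply_fixed_element <- function(tape, v, setup, fe, wavelength, noise) {
  grid <- setup$grid
  switch(fe$type,
    spiral = {
      m <- spiral_mask(grid, fe$charge %||% 1L)
      tr <- mask_transmission(m, grid, noise %||% noise_model(0))
      list(ex = tp_phase(tape, v$ex, tr = tr),
           ey = tp_phase(tape, v$ey, tr = tr))
    },
    lens = {
      m <- lens_mask(grid, fe$focal, wavelength)
      tr <- mask_transmission(m, grid, noise %||% noise_model(0))
      list(ex = tp_phase(tape, v$ex, tr = tr),
           ey = tp_phase(tape, v$ey, tr = tr))
    },
    radial = {
      M <- radial_converter_matrices(grid, fe$alpha %||% 0)
      list(ex = tp_add(tape, c(tp_mulmat(tape, v$ex, M$mxx),
                               tp_mulmat(tape, v$ey, M$mxy))),
           ey = tp_add(tape, c(tp_mulmat(tape, v$ex, M$myx),
                               tp_mulmat(tape, v$ey, M$myy))))
    },
    mask = {
      trh <- mask_transmission(fe$h, grid, noise %||% noise_model(0))
      trv <- mask_transmission(fe$v %||% fe$h, grid, noise %||% noise_model(0))
      list(ex = tp_phase(tape, v$ex, tr = trh),
           ey = tp_phase(tape, v$ey, tr = trv))
    },
    stop("unknown fixed element type: ", fe$type)
  )
}

#' Forward-simulate a grid ansatz to all detectors
#'
#' Propagates every source through its units and beam splitters to the
#' detectors. Sources of equal wavelength superpose coherently; different
#' wavelengths are mutually incoherent and their detected intensities add.
#' Each detector applies Richards-Wolf high-NA focusing onto its camera
#' window. The whole pass is recorded on an adjoint tape, so any scalar
#' objective of the detector fields can be differentiated with respect to
#' every active parameter.
#'
#' @param setup An `ol_ansatz`.
#' @param params Structured parameters from [ansatz_params()].
#' @param active An [active_params()] selection (controls which gradients are
#'   tracked; use the default "none" for plain simulation).
#' @param noise An [noise_model()] or `NULL`.
#' @param kill_edges Integer unit ids whose edges are severed (used when
#'   re-simulating a pruned topology).
#' @return List with `tape`, `detectors` (per detector: port, grid, and
#'   per-wavelength component ids/values), `edge_power` (power reaching the
#'   end of each unit edge), and `source_power`.
#' @export
forward_ansatz <- function(setup, params, active = NULL, noise = NULL,
                           kill_edges = integer(0)) {
  stopifnot(inherits(setup, "ol_ansatz"))
  if (is.null(active)) active <- active_params(setup, bs = FALSE)
  tape <- tape_new()
  groups <- split(seq_along(setup$sources),
                  vapply(setup$sources, function(s) s$wavelength, numeric(1)))
  edge_power <- numeric(setup$audit$units)
  det_out <- lapply(setup$detectors, function(d)
    list(port = d$port, groups = list(), grid = NULL))
  names(det_out) <- vapply(setup$detectors, function(d) d$port, character(1))
  source_power <- 0

  src_edge <- vapply(setup$edges, function(e)
    if (e$kind == "src") e$from$port else "", character(1))
  for (wl_chr in names(groups)) {
    wl <- as.numeric(wl_chr)
    # wires indexed by (node, side): tracked pairs entering each node
    n_nodes <- setup$rows * setup$cols
    in_s <- vector("list", n_nodes); in_w <- vector("list", n_nodes)
    deliver <- function(to, v) {
      if (is.null(v)) return()
      if (to$side == "S") in_s[[to$node]] <<- merge_pair(tape, in_s[[to$node]], v)
      else in_w[[to$node]] <<- merge_pair(tape, in_w[[to$node]], v)
    }
    # source stubs
    for (si in groups[[wl_chr]]) {
      src <- setup$sources[[si]]
      e_idx <- which(src_edge == src$port)
      edge <- setup$edges[[e_idx]]
      f <- ansatz_source_field(setup, src)
      source_power <- source_power + field_power(f)
      v <- list(ex = tp_leaf(tape, f$ex), ey = tp_leaf(tape, f$ey))
      if (edge$uid %in% kill_edges) next
      v <- ansatz_unit(tape, v, setup, params, active, edge$uid, wl, noise)
      edge_power[edge$uid] <- edge_power[edge$uid] + pair_power(tape, v, setup$grid)
      deliver(edge$to, v)
    }
    # nodes in topological order (row-major from the lower-left)
    out_n <- vector("list", n_nodes); out_e <- vector("list", n_nodes)
    for (i in seq_len(setup$rows)) for (j in seq_len(setup$cols)) {
      n <- node_index(setup, i, j)
      a <- in_s[[n]]; b <- in_w[[n]]
      if (is.null(a) && is.null(b)) next
      tname <- if (n %in% active$bs) param_name("bs", n) else NULL
      t_eff <- effective_bs_ratios(
        beam_splitter_params(min(max(params$bs[n], 0), 1)), noise)$t
      ports <- tp_bs(tape, a, b, t_eff, tname)
      out_n[[n]] <- ports$c
      out_e[[n]] <- ports$d
      # feed outgoing edges
      for (e in setup$edges) {
        if (e$from$type != "node" || e$from$node != n) next
        v <- if (e$from$side == "N") ports$c else ports$d
        if (is.null(v) || e$uid %in% kill_edges) next
        v2 <- ansatz_unit(tape, v, setup, params, active, e$uid, wl, noise)
        edge_power[e$uid] <- edge_power[e$uid] + pair_power(tape, v2, setup$grid)
        if (e$to$type == "node") deliver(e$to, v2)
        else if (e$to$port %in% names(det_out)) {
          d <- det_out[[e$to$port]]
          det <- setup$detectors[[which(names(det_out) == e$to$port)]]
          geo <- detector_geometry(setup, det, wl)
          foc <- tp_focus(tape, v2$ex, v2$ey, geo$fp, geo$window)
          d$grid <- window_grid(geo$window)
          d$groups[[wl_chr]] <- list(
            ids = foc,
            ex = tp_val(tape, foc$ex), ey = tp_val(tape, foc$ey),
            ez = tp_val(tape, foc$ez))
          det_out[[e$to$port]] <- d
        }
      }
    }
  }
  list(tape = tape, detectors = det_out, edge_power = edge_power,
       source_power = source_power)
}

merge_pair <- function(tape, a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  list(ex = tp_add(tape, c(a$ex, b$ex)), ey = tp_add(tape, c(a$ey, b$ey)))
}

pair_power <- function(tape, v, grid) {
  if (is.null(v)) return(0)
  (sum(Mod(tp_val(tape, v$ex))^2) + sum(Mod(tp_val(tape, v$ey))^2)) * grid_dA(grid)
}

# detected intensity raster of one detector for one component selector,
# summed incoherently over wavelength groups
detector_intensity <- function(det, component = "transverse") {
  if (length(det$groups) == 0) return(NULL)
  acc <- NULL
  for (g in det$groups) {
    I <- switch(component,
      transverse   = Mod(g$ex)^2 + Mod(g$ey)^2,
      longitudinal = Mod(g$ez)^2,
      total        = Mod(g$ex)^2 + Mod(g$ey)^2 + Mod(g$ez)^2)
    acc <- if (is.null(acc)) I else acc + I
  }
  acc
}

#' Total power detected across all cameras
#'
#' @param fwd Result of [forward_ansatz()].
#' @return Sum over detectors of the camera-window intensity integral.
#' @export
detected_power <- function(fwd) {
  tot <- 0
  for (d in fwd$detectors) {
    I <- detector_intensity(d, "total")
    if (!is.null(I)) tot <- tot + sum(I) * grid_dA(d$grid)
  }
  tot
}

# ---- topology extraction ----------------------------------------------------

#' Extract the discrete topology discovered by the continuous parameters
#'
#' Runs the forward model and keeps only the edges whose arriving power
#' fraction (relative to the total injected source power) reaches
#' `prune_threshold`; the surviving graph is the human-readable blueprint of
#' the discovered setup.
#'
#' @param setup An `ol_ansatz`.
#' @param params Structured parameters.
#' @param prune_threshold Fraction in (0, 1).
#' @param noise Optional [noise_model()].
#' @return An `ol_topology`: data frame of surviving edges (unit id, from,
#'   to, power fraction) plus the node list; JSON-exportable via
#'   [topology_json()].
#' @export
extract_topology <- function(setup, params, prune_threshold = 0.01, noise = NULL) {
  if (!is.finite(prune_threshold) || prune_threshold <= 0 || prune_threshold >= 1)
    stop("'prune_threshold' must lie strictly between 0 and 1")
  fwd <- forward_ansatz(setup, params, noise = noise)
  frac <- fwd$edge_power / fwd$source_power
  keep <- which(frac >= prune_threshold)
  lbl <- function(ep) if (ep$type == "port") ep$port else paste0("BS", ep$node)
  edges <- data.frame(
    uid = keep,
    from = vapply(setup$edges[keep], function(e) lbl(e$from), character(1)),
    to = vapply(setup$edges[keep], function(e) lbl(e$to), character(1)),
    power_fraction = frac[keep],
    stringsAsFactors = FALSE
  )
  structure(list(edges = edges, kept_units = keep,
                 bs = params$bs, threshold = prune_threshold,
                 rows = setup$rows, cols = setup$cols),
            class = "ol_topology")
}

#' @export
print.ol_topology <- function(x, ...) {
  cat(sprintf("<ol_topology> %d surviving edges (threshold %.3g)\n",
              nrow(x$edges), x$threshold))
  if (nrow(x$edges) > 0)
    print(x$edges, row.names = FALSE)
  invisible(x)
}

#' Serialize a topology (or a whole run manifest) to JSON
#'
#' @param topology An `ol_topology`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
topology_json <- function(topology, path = NULL) {
  obj <- list(rows = topology$rows, cols = topology$cols,
              threshold = topology$threshold,
              beam_splitters = topology$bs,
              edges = topology$edges)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

# ---- differentiable objectives over an ansatz -------------------------------

#' Differentiable detector objective of a grid ansatz
#'
#' Builds the discovery loss: every detector's inverse-density loss of the
#' selected intensity component is aggregated with the smooth minimum, so
#' the best-performing detector drives the update while the objective stays
#' differentiable. With `sted` set, the per-detector observable is the
#' Beer-Lambert effective beam computed from the excitation- and
#' depletion-wavelength intensities arriving at that detector; detectors
#' seeing no light contribute nothing.
#'
#' @param setup An `ol_ansatz` (from [build_ansatz()]).
#' @param active An [active_params()] selection.
#' @param cfg An [loss_config()].
#' @param component Intensity observable per detector: `"transverse"`,
#'   `"longitudinal"` or `"total"`.
#' @param sted `NULL`, or `list(params = sted_params(), excitation = <nm>,
#'   depletion = <nm>)` for the effective-beam objective.
#' @param noise Optional [noise_model()] applied during evaluation.
#' @return A `loss_fn` for [optimize_setup()]: maps the packed parameter
#'   vector to `list(value, grad, info)`, where `info$detector` is the
#'   arg-min detector port.
#' @export
ansatz_objective <- function(setup, active, cfg = loss_config(),
                             component = c("transverse", "longitudinal", "total"),
                             sted = NULL, noise = NULL) {
  component <- match.arg(component)
  template <- ansatz_params(setup)
  function(theta) {
    params <- unpack_params(theta, template, setup)
    fwd <- forward_ansatz(setup, params, active, noise)
    losses <- numeric(0); det_seeds <- list(); ports <- character(0)
    for (d in fwd$detectors) {
      ls <- detector_loss_and_seeds(fwd$tape, d, cfg, component, sted)
      if (is.null(ls)) next
      losses <- c(losses, ls$loss)
      det_seeds[[length(det_seeds) + 1L]] <- ls$seeds
      ports <- c(ports, d$port)
    }
    if (length(losses) == 0L) stop("no detector sees any light above threshold")
    value <- softmin(losses, cfg$beta)
    wdet <- softmin_weights(losses, cfg$beta)
    seeds <- list()
    for (i in seq_along(det_seeds)) {
      for (s in det_seeds[[i]]) {
        s$g <- s$g * wdet[i]
        seeds[[length(seeds) + 1L]] <- s
      }
    }
    pgrad <- tape_backward(fwd$tape, seeds)
    list(value = value, grad = pack_grad(pgrad, theta, setup),
         info = list(detector = ports[which.min(losses)],
                     detector_losses = stats::setNames(losses, ports)))
  }
}

# density loss and cotangent seeds of one detector (NULL if dark / below
# threshold)
detector_loss_and_seeds <- function(tape, det, cfg, component, sted) {
  if (length(det$groups) == 0L) return(NULL)
  comp_ids <- function(g) switch(component,
    transverse = list(g$ids$ex, g$ids$ey),
    longitudinal = list(g$ids$ez),
    total = list(g$ids$ex, g$ids$ey, g$ids$ez))
  if (is.null(sted)) {
    I <- detector_intensity(det, component)
    if (max(I) <= 0) return(NULL)
    loss <- density_loss(I, cfg)
    w <- density_loss_grad(I, cfg)
    seeds <- list()
    for (g in det$groups)
      seeds <- c(seeds, intensity_seeds(tape, comp_ids(g), w))
    return(list(loss = loss, seeds = seeds))
  }
  exc <- det$groups[[as.character(sted$excitation)]]
  dep <- det$groups[[as.character(sted$depletion)]]
  if (is.null(exc)) return(NULL)
  I_exc <- switch(component,
    transverse = Mod(exc$ex)^2 + Mod(exc$ey)^2,
    longitudinal = Mod(exc$ez)^2,
    total = Mod(exc$ex)^2 + Mod(exc$ey)^2 + Mod(exc$ez)^2)
  if (max(I_exc) <= 0) return(NULL)
  if (is.null(dep)) {
    I_dep <- matrix(0, nrow(I_exc), ncol(I_exc))
  } else {
    I_dep <- switch(component,
      transverse = Mod(dep$ex)^2 + Mod(dep$ey)^2,
      longitudinal = Mod(dep$ez)^2,
      total = Mod(dep$ex)^2 + Mod(dep$ey)^2 + Mod(dep$ez)^2)
  }
  alpha <- sted$params$alpha
  dmax <- max(I_dep)
  att <- if (dmax > 0) exp(-alpha * I_dep / dmax) else 1
  eff <- I_exc * att
  if (max(eff) <= 0) return(NULL)
  loss <- density_loss(eff, cfg)
  w_eff <- density_loss_grad(eff, cfg)
  seeds <- intensity_seeds(tape, comp_ids(exc), w_eff * att)
  if (!is.null(dep) && dmax > 0) {
    w_dep <- -w_eff * I_exc * att * (alpha / dmax)
    # the normalization max(I_dep) also moves with the depletion raster: its
    # arg-max pixel (locally constant a.e.) receives the compensating term
    pmax_idx <- which.max(I_dep)
    w_dep[pmax_idx] <- w_dep[pmax_idx] +
      sum(w_eff * I_exc * att * alpha * I_dep) / dmax^2
    seeds <- c(seeds, intensity_seeds(tape, comp_ids(dep), w_dep))
  }
  list(loss = loss, seeds = seeds)
}

#' Random initialization of the active parameters of an ansatz
#'
#' Draws beam-splitter transmittances uniformly on the lossless simplex
#' (`T ~ U(0,1)`, `R = 1 - T`), distances uniformly in `z_range`
#' (micrometres), wave-plate angles and SLM phases uniformly in
#' `(-pi, pi]`.
#'
#' @param setup An `ol_ansatz`.
#' @param active An [active_params()] selection.
#' @param z_range Distance range in micrometres (default 1-100 cm).
#' @param z_default Distances of inactive units.
#' @return `function(seed)` producing a packed random parameter vector.
#' @export
ansatz_init_fn <- function(setup, active, z_range = c(1e4, 1e6),
                           z_default = 5e4) {
  template <- ansatz_params(setup, z_default = z_default)
  function(seed) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    p <- template
    p$bs[active$bs] <- stats::runif(length(active$bs))
    p$z1[active$z1] <- stats::runif(length(active$z1), z_range[1], z_range[2])
    p$z2[active$z2] <- stats::runif(length(active$z2), z_range[1], z_range[2])
    p$wp_eta[active$wp] <- stats::runif(length(active$wp), -pi, pi)
    p$wp_theta[active$wp] <- stats::runif(length(active$wp), -pi, pi)
    npx <- setup$grid$ny * setup$grid$nx
    for (i in active$slm) {
      p$slm_h[[i]] <- matrix(stats::runif(npx, -pi, pi), setup$grid$ny, setup$grid$nx)
      p$slm_v[[i]] <- matrix(stats::runif(npx, -pi, pi), setup$grid$ny, setup$grid$nx)
    }
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    pack_params(p, setup, active)
  }
}
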