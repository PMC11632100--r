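# Plain-text / image serialization of fields, masks and traces, and the
# propagation benchmark harness.

#' Export an intensity raster as a 16-bit PNG preview
#'
#' Linear map of `[0, max]` to the full 16-bit range.
#'
#' @param intensity Non-negative numeric matrix.
#' @param path Output file.
#' @export
write_intensity_png <- function(intensity, path) {
  m <- intensity / max(intensity, 1e-300)
  png::writePNG(m[nrow(m):1, , drop = FALSE], path, dpi = NULL)
  invisible(path)
}

#' Export a phase mask as an 8-bit PNG preview
#'
#' Linear map of `(-pi, pi]` to 0..255.
#'
#' @param mask An `ol_phase_mask` or a phase matrix in radians.
#' @param path Output file.
#' @export
write_mask_png <- function(mask, path) {
  v <- if (inherits(mask, "ol_phase_mask")) mask$values else wrap_phase(mask)
  m <- (v + pi) / (2 * pi)
  png::writePNG(m[nrow(m):1, , drop = FALSE], path)
  invisible(path)
}

#' Write / read a field as a CSV container
#'
#' A plain-text serialization: one row per pixel with the real and imaginary
#' parts of every component, preceded by a JSON header line (prefixed `#`)
#' carrying the grid dimensions, pitch and wavelength.
#'
#' @param field An `ol_scalar_field` or `ol_vector_field`.
#' @param path Output path.
#' @export
write_field_csv <- function(field, path) {
  comps <- field_components(field)
  hdr <- jsonlite::toJSON(list(
    nx = field$grid$nx, ny = field$grid$ny, pitch = field$grid$pitch,
    wavelength = field$wavelength, components = names(comps)),
    auto_unbox = TRUE, digits = NA)
  df <- do.call(cbind, lapply(comps, function(m)
    cbind(Re = as.numeric(Re(m)), Im = as.numeric(Im(m)))))
  colnames(df) <- unlist(lapply(names(comps), function(n) paste0(n, c("_re", "_im"))))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", hdr), con)
  utils::write.csv(as.data.frame(df), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_field_csv
#' @return `read_field_csv()` returns the reconstructed field object.
#' @export
read_field_csv <- function(path) {
  hdr <- sub("^#", "", readLines(path, n = 1L))
  meta <- jsonlite::fromJSON(hdr)
  df <- utils::read.csv(path, comment.char = "#")
  grid <- make_grid(meta$nx, meta$ny, meta$pitch)
  get <- function(n) matrix(complex(real = df[[paste0(n, "_re")]],
                                    imaginary = df[[paste0(n, "_im")]]),
                            meta$ny, meta$nx)
  if (identical(sort(meta$components), sort(c("ex", "ey", "ez"))))
    vector_field(grid, get("ex"), get("ey"), get("ez"),
                 wavelength = meta$wavelength)
  else scalar_field(grid, get("u"), meta$wavelength)
}

#' Time the propagation backends
#'
#' A benchmark harness (no pass/fail): median wall time of each propagator
#' at the requested grid sizes.
#'
#' @param sizes Grid sizes (pixels per axis).
#' @param reps Repetitions per timing.
#' @return Data frame with columns `size`, `propagator`, `seconds`.
#' @export
bench_propagators <- function(sizes = c(256, 512), reps = 3) {
  rows <- list()
  for (n in sizes) {
    g <- make_grid(n, n, 2048 / n)
    src <- gaussian_source(g, 650, waist = 2048 / n * n / 8)
    sf <- scalar_field(g, src$ex, 650)
    win <- window_from_grid(g)
    cases <- list(
      rs = function() propagate_rs(sf, 1e4),
      czt = function() propagate_czt(sf, 1e4, win),
      vrs = function() propagate_vrs(src, 1e4),
      vczt = function() propagate_vczt(src, 1e4, win)
    )
    for (nm in names(cases)) {
      t <- vapply(seq_len(reps), function(i)
        system.time(suppressWarnings(cases[[nm]]()))[["elapsed"]], numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(size = n, propagator = nm,
                                              seconds = stats::median(t))
    }
  }
  do.call(rbind, rows)
}
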