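# Grid-ansatz wiring, audits, parameter accounting, layout counting,
# forward passivity and topology extraction.

test_that("the default 3x3 ansatz reproduces the canonical element audit", {
  a <- build_ansatz(ansatz_spec(3, 3))
  expect_identical(a$audit$bs, 9L)
  expect_identical(a$audit$sslm, 24L)
  expect_identical(a$audit$slm_panels, 48L)
  expect_identical(a$audit$wave_plates, 24L)
  expect_identical(a$audit$source_ports, 6L)
  expect_identical(a$audit$detector_ports, 6L)
  expect_identical(a$audit$internal_edges, 12L)
  expect_identical(a$audit$external_stubs, 12L)
})

test_that("audit identities hold over lattice sizes, including 1x1 and 6x6", {
  for (r in 1:4) for (cc in 1:4) {
    a <- build_ansatz(ansatz_spec(r, cc))
    expect_identical(a$audit$units,
                     r * (cc - 1L) + cc * (r - 1L) + 2L * (r + cc))
    expect_identical(a$audit$bs, r * cc)
  }
  a1 <- build_ansatz(ansatz_spec(1, 1))
  expect_identical(a1$audit$units, 4L)       # four external stubs
  a6 <- build_ansatz(ansatz_spec(6, 6))      # the large-lattice variant builds
  expect_identical(a6$audit$units, 84L)
  expect_identical(a6$audit$slm_panels, 168L)
})

test_that("port assignment is validated", {
  g <- make_grid(16, 16, 10)
  expect_error(ansatz_spec(2, 2, grid = g,
    sources = list(list(port = "N1", wavelength = 650))), "input stubs")
  expect_error(ansatz_spec(2, 2, grid = g,
    sources = list(list(port = "S1", wavelength = 650),
                   list(port = "S1", wavelength = 532))), "distinct")
})

test_that("parameter counting matches the configuration arithmetic", {
  a <- build_ansatz(ansatz_spec(3, 3, mode = "fixed_masks",
                                fixed_elements = list("1" = list(type = "spiral"))))
  units <- c(1L, 2L, 19L, 20L)
  act <- active_params(a, bs = TRUE, z1 = units, z2 = units, wp = units)
  expect_equal(count_parameters(a, act), 25)
  expect_equal(count_parameters(a, active_params(a, bs = FALSE)), 0)
  # highly parameterized configuration: 6 panels of 824^2 + 6 wave-plate
  # scalars + 8 distances
  a7 <- build_ansatz(ansatz_spec(3, 3, grid = make_grid(824, 824, 6.06)))
  act7 <- active_params(a7, bs = FALSE, z1 = units, z2 = units,
                        wp = c(1L, 2L, 19L), slm = c(1L, 2L, 19L))
  expect_equal(count_parameters(a7, act7), 4073870)
  # SLM-raster dominated count equals the audit formula
  expect_equal(count_parameters(a7, act7),
               6 * 824^2 + 6 + 8)
})

test_that("pack/unpack round-trips and the packed length equals the count", {
  a <- small_ansatz()
  act <- active_params(a, bs = TRUE, z1 = c(1L, 3L), z2 = 2L, wp = c(4L, 5L),
                       slm = 1L)
  p <- ansatz_params(a)
  p$bs <- runif(a$audit$bs)
  p$z1 <- runif(a$audit$units, 1e4, 5e4)
  p$wp_eta <- runif(a$audit$units, -pi, pi)
  p$slm_h[[1]] <- matrix(runif(a$grid$ny * a$grid$nx, -pi, pi),
                         a$grid$ny, a$grid$nx)
  v <- pack_params(p, a, act)
  expect_equal(length(v), count_parameters(a, act))
  p2 <- unpack_params(v, ansatz_params(a), a)
  expect_equal(p2$bs[act$bs], p$bs[act$bs])
  expect_equal(p2$z1[act$z1], p$z1[act$z1])
  expect_equal(p2$slm_h[[1]], p$slm_h[[1]])
  v2 <- pack_params(p2, a, act)
  expect_equal(as.numeric(v2), as.numeric(v))
})

test_that("discrete layout counts are exact, including the enumeration oracle", {
  expect_equal(count_discrete_layouts(0, 0, 0)$string, "1")
  # brute-force enumeration of all (bs_state, slm_on, wp_on) tuples
  states <- expand.grid(bs = 1:3, slm = 0:1, wp = 0:1)
  expect_equal(count_discrete_layouts(1, 1, 1)$approx, nrow(states))
  expect_identical(count_discrete_layouts(1, 1, 1)$string, "12")
  full <- count_discrete_layouts(9, 48, 24)
  expect_identical(full$string, "92950339482323226741178368")  # 3^9 * 2^72
  expect_equal(full$log10, 25.968, tolerance = 1e-3)
  # element-arrangement count: 10 slots over 5 types ~ 10 million
  arr <- count_arrangements(10, 5)
  expect_identical(arr$string, "9765625")
  expect_equal(round(arr$approx / 1e7), 1)
})

test_that("a fully transmissive ansatz routes each source straight through", {
  a <- small_ansatz()
  p <- ansatz_params(a, z_default = 2e4)
  p$bs[] <- 1   # transmit S -> N everywhere
  fwd <- forward_ansatz(a, p)
  # S1 feeds column 1 -> N1; W2 (row 2, west) reflects nowhere: transmitted
  # along the row to the east detector ports, which carry no camera here
  expect_gt(sum(detector_intensity(fwd$detectors[["N1"]], "total")), 0)
  expect_lte(detected_power(fwd), fwd$source_power * (1 + 1e-9))
})

test_that("the network is passive for random parameter draws", {
  a <- small_ansatz()
  act <- active_params(a, bs = TRUE, z1 = TRUE, z2 = TRUE, wp = TRUE,
                       slm = c(1L, 2L))
  init_fn <- ansatz_init_fn(a, act, z_range = c(5e3, 5e4), z_default = 2e4)
  for (s in 1:25) {
    th <- init_fn(1000L + s)
    p <- unpack_params(th, ansatz_params(a), a)
    fwd <- forward_ansatz(a, p)
    expect_lte(detected_power(fwd), fwd$source_power * (1 + 1e-6))
  }
})

test_that("topology extraction prunes dark edges and keeps the blueprint", {
  a <- small_ansatz()
  p <- ansatz_params(a, z_default = 2e4)
  p$bs[] <- 0.999  # nearly fully transmissive: one dominant path per source
  topo <- extract_topology(a, p, prune_threshold = 0.05)
  expect_true(all(topo$edges$power_fraction >= 0.05))
  # threshold -> 0 retains every lit edge
  topo0 <- extract_topology(a, p, prune_threshold = 1e-9)
  expect_gte(nrow(topo0$edges), nrow(topo$edges))
  expect_error(extract_topology(a, p, prune_threshold = 1.2), "between 0 and 1")
  js <- topology_json(topo)
  expect_true(jsonlite::validate(js))
  # pruned re-simulation: severing sub-threshold edges (< 0.1% power)
  # reproduces the detector image within 1%
  topoc <- extract_topology(a, p, prune_threshold = 1e-3)
  kill <- setdiff(seq_len(a$audit$units), topoc$kept_units)
  full <- forward_ansatz(a, p)
  pruned <- forward_ansatz(a, p, kill_edges = kill)
  # deviations are judged against the overall detection scale: a detector fed
  # only by sub-threshold edges goes dark, which is exactly the blueprint
  # reading of the pruned graph
  scale_ref <- max(vapply(full$detectors, function(d) {
    I <- detector_intensity(d, "total"); if (is.null(I)) 0 else max(I)
  }, numeric(1)))
  for (port in c("N1", "N2")) {
    I_full <- detector_intensity(full$detectors[[port]], "total")
    I_pruned <- detector_intensity(pruned$detectors[[port]], "total")
    if (is.null(I_full)) next
    if (is.null(I_pruned)) I_pruned <- 0 * I_full
    expect_lt(max(abs(I_full - I_pruned)) / scale_ref, 0.01)
  }
})

test_that("sources of different wavelengths add incoherently at detectors", {
  a <- small_ansatz()
  p <- ansatz_params(a, z_default = 2e4)
  p$bs[] <- 0.5
  fwd <- forward_ansatz(a, p)
  d <- fwd$detectors[["N1"]]
  expect_setequal(names(d$groups), c("650", "532"))
  I_sum <- detector_intensity(d, "total")
  g1 <- d$groups[["650"]]; g2 <- d$groups[["532"]]
  manual <- Mod(g1$ex)^2 + Mod(g1$ey)^2 + Mod(g1$ez)^2 +
    Mod(g2$ex)^2 + Mod(g2$ey)^2 + Mod(g2$ez)^2
  expect_equal(I_sum, manual, tolerance = 1e-12)
})
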