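# Fixture generators, the ideal 4f relay, and the robustness protocol.

test_that("mask generators are deterministic and geometrically correct", {
  g <- make_grid(256, 256, 1)
  d <- make_mask(g, "delta")
  expect_equal(sum(d), 1)
  expect_equal(d[which.min(abs(g$y)), which.min(abs(g$x))], 1)
  tri <- make_mask(g, "triangle", size_fraction = 0.3)
  expect_true(all(tri %in% c(0, 1)))
  b <- 0.3 * 256; h <- 0.3 * 256
  expect_equal(sum(tri) * grid_dA(g), 0.5 * b * h, tolerance = 0.04)
  r1 <- make_mask(g, "random_shapes", seed = 5)
  r2 <- make_mask(g, "random_shapes", seed = 5)
  expect_identical(r1, r2)
  expect_false(identical(r1, make_mask(g, "random_shapes", seed = 6)))
  blob <- make_mask(g, "blob_logo", seed = 3)
  expect_true(all(blob %in% c(0, 1)) && sum(blob) > 0)
})

test_that("the dataset target map is the ideal point-reflected scaling", {
  g <- make_grid(64, 64, 4)
  # a delta at (x, y) maps to a delta at (-2x, -2y)
  d <- matrix(0, 64, 64)
  ix <- which.min(abs(g$x - 20)); iy <- which.min(abs(g$y - 12))
  d[iy, ix] <- 1
  t <- imaging_map(d, g, 2)
  peak <- which(t == max(t), arr.ind = TRUE)[1, ]
  expect_equal(g$x[peak[2]], -40, tolerance = 4)
  expect_equal(g$y[peak[1]], -24, tolerance = 4)
  # a centered symmetric disk is inversion-invariant: target = scaled disk
  X <- matrix(g$x, 64, 64, byrow = TRUE); Y <- matrix(g$y, 64, 64)
  disk <- (X^2 + Y^2 <= 30^2) * 1
  td <- imaging_map(disk, g, 2)
  expect_gt(cor(as.numeric(td), as.numeric((X^2 + Y^2 <= 60^2) * 1)), 0.95)
  ds <- make_4f_dataset(5, 2, g, seed = 2)
  expect_length(ds, 5)
  expect_identical(ds[[3]]$target, imaging_map(ds[[3]]$input^2, g, 2))
})

test_that("the ideal 4f relay magnifies by f2/f1 and inverts", {
  g <- make_grid(320, 320, 3)
  tri <- make_mask(g, "triangle", size_fraction = 0.4)
  r <- quiet(run_4f_reference(6000, 12000, tri, g, 650))
  expect_equal(r$magnification, 2, tolerance = 0.04)
  expect_true(r$inverted)
  r1 <- quiet(run_4f_reference(8000, 8000, tri, g, 650))
  expect_equal(r1$magnification, 1, tolerance = 0.04)
  expect_true(r1$inverted)
  r3 <- quiet(run_4f_reference(5000, 15000, tri, g, 650))
  expect_equal(r3$magnification, 3, tolerance = 0.06)
})

test_that("the generator and the physical 4f relay agree on training masks", {
  g <- make_grid(256, 256, 3)
  ds <- make_4f_dataset(2, 2, g, seed = 2001)
  for (pair in ds) {
    physical <- quiet(run_4f_reference(10000, 20000, pair$input, g, 650))$image
    ideal <- pair$target
    physical <- physical / sum(physical); ideal <- ideal / sum(ideal)
    # MSE relative to the target power (mean squared target intensity)
    expect_lt(mean((physical - ideal)^2) / mean(ideal^2), 0.02)
  }
})

test_that("batch-averaged training loss equals the mean of pair losses", {
  g <- make_grid(32, 32, 10)
  ds <- make_4f_dataset(6, 2, g, seed = 4)
  task <- magnifier_task(ds, g, batch = 6, seed = 1)
  r <- task$objective(task$init)
  individual <- task$pair_losses(task$init, ds)
  expect_equal(r$value, mean(individual), tolerance = 1e-12)
})

test_that("robustness: zero noise is exact, standard beats stress, 8-bit runs", {
  g <- make_grid(64, 64, 6)
  tri <- make_mask(g, "triangle", size_fraction = 0.4)
  masks <- list(lens_mask(g, 2500, 650)$values, lens_mask(g, 5000, 650)$values)
  zs <- c(2500, 7500, 5000)
  tab <- run_robustness(masks, zs, tri, g, 650, seed = 3L)
  expect_setequal(tab$level, c("none", "standard", "stress", "stress_8bit"))
  expect_equal(tab$nmse[tab$level == "none"], 0)
  expect_lt(tab$nmse[tab$level == "standard"],
            tab$nmse[tab$level == "stress"])
  expect_true(is.finite(tab$nmse[tab$level == "stress_8bit"]))
  # deterministic given the seed
  tab2 <- run_robustness(masks, zs, tri, g, 650, seed = 3L)
  expect_identical(tab, tab2)
})

test_that("preset configurations expose the documented parameter counts", {
  p <- preset_config("sted_topology", resolution = 32, steps = 1, restarts = 1)
  expect_equal(length(p$init), 25)
  expect_equal(count_parameters(p$setup, p$active), 25)
  p2 <- preset_config("magnifier_4f", resolution = 64, steps = 1, restarts = 1)
  expect_equal(length(p2$init), 2 * 32^2 + 3)
  # zero-step preset run reports on the random initialization only
  res <- run_preset(preset_config("sharp_focus_topology", resolution = 32,
                                  steps = 0, restarts = 1))
  expect_true(is.na(res$run$best_value))
  expect_length(res$run$traces[[1]], 0)
})

test_that("png and topology artifacts are written by run_preset", {
  out <- tempfile("preset")
  res <- run_preset(preset_config("sted_topology", resolution = 32,
                                  steps = 3, restarts = 1), out_dir = out)
  expect_true(file.exists(file.path(out, "loss_trace.csv")))
  expect_true(file.exists(file.path(out, "topology.json")))
  expect_true(file.exists(file.path(out, "manifest.json")))
})
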