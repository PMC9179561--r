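test_that("cell masks are 4-connected, non-empty and morphologically sensible", {
  set.seed(701)
  for (rep in 1:10) {
    ret <- stats::runif(1)
    px <- make_cell_mask(cell_shape_params(retraction = ret), 1)
    expect_gt(nrow(px), 0)
    m <- px_to_mask(cbind(px[, 1] - min(px[, 1]), px[, 2] - min(px[, 2])),
                    c(max(px[, 2]) - min(px[, 2]) + 1L,
                      max(px[, 1]) - min(px[, 1]) + 1L))
    expect_equal(max(label_components(m, 4)), 1L)
  }
})

test_that("the amoeboid limit is near-convex and the ramified limit is not", {
  set.seed(702)
  ri_amoeboid <- mean(vapply(1:10, function(i) {
    px <- make_cell_mask(cell_shape_params(soma_radius_um = 5, retraction = 1), 1)
    mask_morphometry(px, 1)$RI
  }, numeric(1)))
  expect_gt(ri_amoeboid, 0.9)
  # soma-only cell (no processes) is a disk
  px <- make_cell_mask(cell_shape_params(n_processes = 0, retraction = 0,
                                         soma_radius_um = 8), 1)
  expect_gt(mask_morphometry(px, 1)$RI, 0.9)
  ri_ramified <- mean(vapply(1:10, function(i) {
    px <- make_cell_mask(cell_shape_params(n_processes = 6,
                                           process_length_um = 25,
                                           retraction = 0), 1)
    mask_morphometry(px, 1)$RI
  }, numeric(1)))
  expect_lt(ri_ramified, 0.7)
})

test_that("a too-coarse raster for the soma is rejected", {
  expect_error(make_cell_mask(cell_shape_params(soma_radius_um = 1), 1),
               "3 pixels")
})

test_that("calibrate_retraction inverts the mean-RI response", {
  # self-consistency: measure at a retraction, then invert the measurement
  target <- with_preserved_seed(760013, {
    mean(vapply(1:25, function(i) {
      px <- make_cell_mask(cell_shape_params(retraction = 0.5), 1)
      mask_morphometry(px, 1)$RI
    }, numeric(1)))
  })
  ret <- calibrate_retraction(target)
  expect_lt(abs(ret - 0.5), 0.1)
  # monotonicity probe
  r_low <- calibrate_retraction(0.55)
  r_high <- calibrate_retraction(0.85)
  expect_gt(r_high, r_low)
  # out-of-range target reports the achievable interval
  expect_error(calibrate_retraction(0.999), "achievable")
})

test_that("render_scene handles the empty scene and reports exact arithmetic", {
  set.seed(703)
  roi <- roi_polygon(rbind(c(10, 10), c(210, 10), c(210, 210), c(10, 210)))
  sc0 <- render_scene(0, cell_shape_params(), roi, shape = c(220, 220))
  expect_equal(sc0$truth$true_count, 0)
  expect_equal(sc0$truth$true_positive_fraction_pct, 0)
  expect_equal(length(sc0$truth$cell_masks), 0)
  # 12 cells in a 0.05 mm^2 ROI -> 240 cells/mm^2 (ROI ~ 223.6 px square)
  s <- sqrt(0.05) * 1000
  roi2 <- roi_polygon(rbind(c(30, 30), c(30 + s, 30), c(30 + s, 30 + s),
                            c(30, 30 + s)))
  sc <- render_scene(12, cell_shape_params(retraction = 0.8), roi2,
                     shape = c(300, 300))
  expect_equal(sc$truth$true_density_cells_per_mm2, 240.0, tolerance = 1e-9)
})

test_that("infeasible placement densities raise a placement error", {
  roi <- roi_polygon(rbind(c(10, 10), c(60, 10), c(60, 60), c(10, 60)))
  set.seed(704)
  expect_error(
    render_scene(50, cell_shape_params(), roi, shape = c(80, 80),
                 max_tries = 20L),
    "placement error")
})

test_that("scene ground truth is self-consistent with the emitted masks", {
  set.seed(705)
  roi <- roi_polygon(rbind(c(30, 30), c(350, 30), c(350, 350), c(30, 350)))
  sc <- render_scene(9, cell_shape_params(retraction = 0.4), roi,
                     shape = c(380, 380))
  tr <- sc$truth
  expect_equal(tr$true_count, length(tr$cell_masks))
  expect_equal(tr$true_count, nrow(tr$cell_centroids))
  expect_equal(tr$true_density_cells_per_mm2,
               tr$true_count / roi_area_mm2(roi, 1))
  # recompute the positive fraction and per-cell RI from the masks
  rm <- rasterize_roi(roi, c(380, 380))
  fg <- matrix(FALSE, 380, 380)
  for (p in tr$cell_masks) fg[p[, 2] + 1L + p[, 1] * 380L] <- TRUE
  expect_equal(100 * sum(fg & rm) / sum(rm), tr$true_positive_fraction_pct)
  ri <- vapply(tr$cell_masks, function(p) mask_morphometry(p, 1)$RI,
               numeric(1))
  expect_equal(ri, tr$true_ri_per_cell)
})

test_that("cohort generation is deterministic and bookkeeps correctly", {
  spec <- cohort_spec(
    list(group_spec("Ctrl", 2, target_mean_ri = 0.6, sd_ri = 0.03,
                    target_density = 60, sd_density = 10),
         group_spec("5w", 2, target_mean_ri = 0.85, sd_ri = 0.03,
                    target_density = 120, sd_density = 10)),
    seed = 314, image_shape = c(320, 320))
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_equal(length(c1$scenes), 4)
  expect_equal(nrow(c1$manifest), 4)
  expect_identical(c1$manifest, c2$manifest)
  expect_identical(c1$scenes[[3]]$image$pixels, c2$scenes[[3]]$image$pixels)
  # group targets separate morphologies
  m <- c1$manifest
  expect_gt(mean(m$true_mean_ri[m$group == "5w"]),
            mean(m$true_mean_ri[m$group == "Ctrl"]))
})

test_that("generator cohorts track their RI target across seeds", {
  # Monte-Carlo check of the generator against its own contract: per-animal
  # true mean RI drawn around 0.66 (SD 0.04) must average back to 0.66
  grand <- vapply(1:6, function(s) {
    spec <- cohort_spec(
      list(group_spec("Ctrl", 5, target_mean_ri = 0.66, sd_ri = 0.04,
                      target_density = 90, sd_density = 15)),
      seed = 2000 + s, image_shape = c(320, 320))
    mean(generate_cohort(spec)$manifest$true_mean_ri)
  }, numeric(1))
  expect_lt(abs(mean(grand) - 0.66), 0.06)
})

test_that("cohort YAML round-trips through the generator interface", {
  d <- withr::local_tempdir()
  yml <- file.path(d, "cohort.yaml")
  writeLines(c(
    "seed: 99",
    "image_shape: [320, 320]",
    "pixel_size_um: 1",
    "groups:",
    "  - label: Ctrl",
    "    n_animals: 2",
    "    target_mean_ri: 0.6",
    "    sd_ri: 0.02",
    "    target_density: 50",
    "    sd_density: 5"), yml)
  spec <- read_cohort_yaml(yml)
  expect_s3_class(spec, "cohort_spec")
  expect_equal(spec$seed, 99L)
  expect_equal(spec$groups[[1]]$target_density, 50)
  co <- generate_cohort(spec)
  out <- file.path(d, "cohort_out")
  write_cohort(co, out)
  expect_true(file.exists(file.path(out, "manifest.csv")))
  expect_true(file.exists(file.path(out, "truth_cells.csv")))
  man <- utils::read.csv(file.path(out, "manifest.csv"))
  expect_equal(nrow(man), 2)
  expect_true(all(file.exists(file.path(out, man$file))))
  # scenes written as PNG read back bit-identically
  img <- read_image(file.path(out, man$file[1]), 1)
  expect_equal(img$pixels, co$scenes[[1]]$image$pixels)
})

test_that("group_spec validates target ranges", {
  expect_error(group_spec("g", 1, target_mean_ri = 0.5, target_density = 10))
  expect_error(group_spec("g", 5, target_mean_ri = 0.5), "exactly one")
  expect_error(group_spec("g", 5, target_mean_ri = 0.5, target_density = 10,
                          target_positive_pct = 5), "exactly one")
  expect_error(group_spec("g", 5, target_mean_ri = 1.5, target_density = 10))
  expect_error(group_spec("g", 5, target_mean_ri = 0.5,
                          target_positive_pct = 105), "\\(0, 100\\)")
})
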