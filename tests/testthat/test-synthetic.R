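test_that("ground truth respects the minimum center distance and image bounds", {
  cfg <- simulation_config(image_shape = c(512L, 512L), n_cells = 200L,
                           min_center_distance_px = 12, rng_seed = 7L)
  gt <- generate_ground_truth(cfg)
  expect_equal(nrow(gt$centers), 200)
  d <- as.matrix(dist(gt$centers))
  diag(d) <- Inf
  expect_gte(min(d), 12)
  expect_true(all(gt$centers >= 1 & gt$centers[, 1] <= 512 & gt$centers[, 2] <= 512))
})

test_that("zero cells yields an empty ground truth and impossible density errors", {
  cfg0 <- simulation_config(n_cells = 0L, image_shape = c(128L, 128L),
                            border_margin_px = 10)
  gt0 <- generate_ground_truth(cfg0)
  expect_equal(nrow(gt0$centers), 0)
  expect_length(gt0$phenotype, 0)
  # far more cells than the frame can hold at this spacing
  cfg_full <- simulation_config(n_cells = 500L, image_shape = c(96L, 96L),
                                min_center_distance_px = 12, border_margin_px = 8)
  expect_error(generate_ground_truth(cfg_full, max_attempts_per_cell = 50L),
               "capacity")
})

test_that("phenotypes reproduce an independent re-draw of the seeded multinomial stream", {
  cfg <- simulation_config(image_shape = c(1024L, 1024L), n_cells = 1000L,
                           phenotype_frequencies = c(KC = 0.5, MoMF = 0.5),
                           min_center_distance_px = 8, nucleus_radius_px = 4,
                           rng_seed = 7L)
  gt <- generate_ground_truth(cfg)
  oracle <- withr::with_seed(7L + 13L,
    sample(c("KC", "MoMF"), 1000L, replace = TRUE, prob = c(0.5, 0.5)))
  expect_identical(gt$phenotype, oracle)
})

test_that("observed phenotype frequencies sit within 4 standard errors of targets", {
  cfg <- simulation_config(image_shape = c(1024L, 1024L), n_cells = 1000L,
                           min_center_distance_px = 10, rng_seed = 3L)
  gt <- generate_ground_truth(cfg)
  for (p in names(cfg$phenotype_frequencies)) {
    target <- cfg$phenotype_frequencies[[p]]
    se <- sqrt(target * (1 - target) / 1000)
    expect_lt(abs(mean(gt$phenotype == p) - target), 4 * se)
  }
})

test_that("same seed gives bit-identical ground truth and rendered images", {
  cfg <- simulation_config(image_shape = c(192L, 192L), n_cells = 25L,
                           n_cycles = 2L, border_margin_px = 24, rng_seed = 42L)
  panel <- default_panel(2L)
  g1 <- generate_ground_truth(cfg); g2 <- generate_ground_truth(cfg)
  expect_identical(g1$centers, g2$centers)
  expect_identical(g1$amplitudes, g2$amplitudes)
  expect_identical(g1$cycle_transforms[[2]]$matrix, g2$cycle_transforms[[2]]$matrix)
  c1 <- render_cycles(g1, cfg, panel); c2 <- render_cycles(g2, cfg, panel)
  expect_identical(c1, c2)
})

test_that("with identity transforms and zero noise the nuclear channels are pixel-identical", {
  sc <- clean_scene()
  expect_identical(sc$cycles[[1]]$DAPI, sc$cycles[[2]]$DAPI)
  expect_identical(sc$cycles[[1]]$DAPI, sc$cycles[[3]]$DAPI)
})

test_that("a rendered spot integrates to amplitude * 2*pi*sigma^2 within 1%", {
  cfg <- simulation_config(image_shape = c(128L, 128L), n_cells = 1L,
                           background = c(0, 0), af_amplitude = 0, noise_sd = 0,
                           n_cycles = 1L, cycle_transforms = identity_transforms(1),
                           border_margin_px = 50, rng_seed = 2L)
  gt <- generate_ground_truth(cfg)
  panel <- panel_config(cycles = list(c(c1 = "DAPI", c2 = "IBA1")),
                        nuclear_channel = "DAPI")
  cy <- render_cycles(gt, cfg, panel)
  sigma <- cfg$nucleus_radius_px / 2
  a <- unname(gt$amplitudes[1, "DAPI"])
  expect_equal(sum(cy[[1]]$DAPI), a * 2 * pi * sigma^2, tolerance = 0.01)
})

test_that("without autofluorescence, disjoint-support marker channels are uncorrelated", {
  cfg <- simulation_config(image_shape = c(384L, 384L), n_cells = 30L,
                           background = c(0, 0), af_amplitude = 0, noise_sd = 0,
                           n_cycles = 3L, cycle_transforms = identity_transforms(3),
                           phenotype_frequencies = c(MoMF = 0.5, ductular = 0.5),
                           border_margin_px = 24, rng_seed = 9L)
  gt <- generate_ground_truth(cfg)
  cy <- render_cycles(gt, cfg, default_panel(3L))
  # IBA1 (MoMF only) and CK19 (ductular only) have disjoint cell support
  expect_lte(abs(cor(as.vector(cy[[1]]$IBA1), as.vector(cy[[2]]$CK19))), 0.02)
})

test_that("trichrome rendering places collagen in the blue band over a white background", {
  sc <- tumor_scene()
  rgb <- render_trichrome(sc$gt, sc$cfg)
  hsv <- grDevices::rgb2hsv(r = as.vector(rgb[, , 1]), g = as.vector(rgb[, , 2]),
                            b = as.vector(rgb[, , 3]), maxColorValue = 1)
  blue_band <- matrix(hsv[1, ] >= 0.55 & hsv[1, ] <= 0.65 & hsv[2, ] >= 0.5,
                      nrow(rgb), ncol(rgb))
  # blue-band pixels are exactly the collagen mask
  expect_identical(blue_band, sc$gt$collagen_mask)
  # background (neither tissue nor collagen) stays near-white
  tissue_or_col <- sc$gt$collagen_mask | (matrix(hsv[2, ], nrow(rgb)) >= 0.1)
  bg_sat <- hsv[2, ][!as.vector(tissue_or_col)]
  expect_true(all(bg_sat < 0.1))
})

test_that("an empty collagen mask renders no blue-band pixel", {
  sc <- clean_scene()
  rgb <- render_trichrome(sc$gt, sc$cfg)
  hsv <- grDevices::rgb2hsv(r = as.vector(rgb[, , 1]), g = as.vector(rgb[, , 2]),
                            b = as.vector(rgb[, , 3]), maxColorValue = 1)
  expect_false(any(hsv[1, ] >= 0.55 & hsv[1, ] <= 0.65 & hsv[2, ] >= 0.5))
})
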