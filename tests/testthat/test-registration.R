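test_that("warp with the identity leaves images unchanged and fully valid", {
  img <- matrix(runif(64 * 64), 64, 64)
  w <- warp_image(img, affine_identity())
  expect_equal(w$image, img, tolerance = 1e-12)
  expect_true(all(w$valid))
})

test_that("warp by a pure translation vacates exactly the shifted rows", {
  img <- matrix(runif(64 * 64, 1, 2), 64, 64)
  t10 <- affine_transform(cbind(diag(2), c(10, 0)))
  w <- warp_image(img, t10)
  expect_false(any(w$valid[1:10, ]))
  expect_true(all(w$valid[11:64, ]))
  expect_equal(w$image[11:64, ], img[1:54, ], tolerance = 1e-12)
})

test_that("warp round trip t then t^-1 returns close to the original", {
  sc <- clean_scene()
  img <- sc$cycles[[1]]$DAPI
  t <- affine_from_params(rotation_deg = 2, scale = 1.01, translation = c(5, -3),
                          center = c(128.5, 128.5))
  fwd <- warp_image(img, t)
  back <- warp_image(fwd$image, affine_invert(t))
  both <- back$valid & warp_image(fwd$valid * 1, affine_invert(t), interpolation = "nearest")$image > 0
  mad <- mean(abs(back$image[both] - img[both]))
  expect_lt(mad, 0.01 * diff(range(img)))
})

test_that("warp conserves total intensity within 1% for interior translations", {
  img <- matrix(0, 128, 128)
  img <- add_disc(img, c(64, 64), 20, 37.5)
  t <- affine_transform(cbind(diag(2), c(7.3, -4.6)))
  w <- warp_image(img, t)
  expect_equal(sum(w$image), sum(img), tolerance = 0.01)
})

test_that("registering an image to itself returns the identity", {
  sc <- clean_scene()
  t <- estimate_affine(sc$cycles[[1]]$DAPI, sc$cycles[[1]]$DAPI)
  expect_lt(max(abs(t$matrix[, 3])), 0.1)
  expect_lt(max(abs(t$matrix[, 1:2] - diag(2))), 1e-3)
  expect_error(estimate_affine(matrix(1, 32, 32), matrix(1, 32, 32)), "constant")
})

test_that("a known translation of a synthetic DAPI field is recovered within 0.5 px", {
  cfg <- simulation_config(image_shape = c(512L, 512L), n_cells = 300L,
                           min_center_distance_px = 10, n_cycles = 2L,
                           cycle_transforms = list(affine_identity(),
                                                   affine_transform(cbind(diag(2), c(12, -7)))),
                           rng_seed = 21L)
  gt <- generate_ground_truth(cfg)
  cy <- render_cycles(gt, cfg, default_panel(2L))
  est <- estimate_affine(cy[[1]]$DAPI, cy[[2]]$DAPI)
  expect_lt(max(abs(est$matrix[, 3] - c(12, -7))), 0.5)
})

test_that("rotation plus shift maps true centers back within 1 px mean error", {
  true_t <- affine_from_params(rotation_deg = 2, translation = c(5, 5),
                               center = c(192.5, 192.5))
  cfg <- simulation_config(image_shape = c(384L, 384L), n_cells = 150L,
                           min_center_distance_px = 10, n_cycles = 2L,
                           cycle_transforms = list(affine_identity(), true_t),
                           rng_seed = 22L)
  gt <- generate_ground_truth(cfg)
  cy <- render_cycles(gt, cfg, default_panel(2L))
  est <- estimate_affine(cy[[1]]$DAPI, cy[[2]]$DAPI)
  expect_lte(landmark_error(true_t, est, gt$centers[1:50, , drop = FALSE]), 1)
})

test_that("align_experiment handles the single-cycle case and missing nuclear channels", {
  sc <- clean_scene()
  one <- align_experiment(sc$cycles[1], sc$panel)
  expect_identical(one$cycles[[1]], sc$cycles[[1]])
  expect_equal(one$transforms[[1]]$matrix, affine_identity()$matrix)
  broken <- sc$cycles
  names(broken[[2]])[1] <- "NOPE"
  expect_error(align_experiment(broken, sc$panel), "nuclear channel")
})

test_that("composing estimated pairwise transforms agrees with the direct estimate", {
  cfg <- simulation_config(image_shape = c(384L, 384L), n_cells = 150L,
                           min_center_distance_px = 10, n_cycles = 3L,
                           max_translation_px = 8, max_rotation_deg = 2,
                           noise_sd = 0, rng_seed = 31L)
  gt <- generate_ground_truth(cfg)
  cy <- render_cycles(gt, cfg, default_panel(3L))
  ab <- estimate_affine(cy[[2]]$DAPI, cy[[1]]$DAPI) # cycle1 -> cycle2 frame
  bc <- estimate_affine(cy[[3]]$DAPI, cy[[2]]$DAPI)
  direct <- estimate_affine(cy[[3]]$DAPI, cy[[1]]$DAPI)
  composed <- affine_compose(bc, ab)
  pts <- gt$centers[1:50, , drop = FALSE]
  err <- mean(sqrt(rowSums((affine_apply(composed, pts) - affine_apply(direct, pts))^2)))
  expect_lte(err, 2)
})

test_that("crop_common_region returns the full frame for all-true masks", {
  m <- matrix(TRUE, 40, 60)
  expect_equal(crop_common_region(list(m, m)),
               c(row0 = 0L, col0 = 0L, row1 = 40L, col1 = 60L))
})

test_that("crop after a pure translation loses exactly the vacated band", {
  img <- matrix(1, 50, 50)
  w <- warp_image(img, affine_transform(cbind(diag(2), c(10, 0))))
  rect <- crop_common_region(list(matrix(TRUE, 50, 50), w$valid))
  expect_equal(rect[["row1"]] - rect[["row0"]], 40)
  expect_equal(rect[["col1"]] - rect[["col0"]], 50)
  cropped <- crop_apply(img, rect)
  expect_equal(dim(cropped), c(40, 50))
})

test_that("disjoint validity masks cannot be cropped", {
  a <- matrix(FALSE, 20, 20); a[1:5, ] <- TRUE
  b <- matrix(FALSE, 20, 20); b[15:20, ] <- TRUE
  expect_error(crop_common_region(list(a, b)), "empty intersection")
})
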