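test_that("pixel feature bank has the expected planes and zero gradients on constants", {
  f <- compute_pixel_features(matrix(5, 32, 32), scales = c(1, 2, 4))
  expect_equal(dim(f)[3], 10) # raw + 3 per scale
  for (s in c(1, 2, 4)) {
    expect_equal(max(abs(f[, , paste0("gradmag_", s)])), 0)
    expect_equal(max(abs(f[, , paste0("log_", s)])), 0, tolerance = 1e-10)
  }
  expect_error(compute_pixel_features(matrix(5, 32, 32), scales = c(0, 2)), "positive")
})

test_that("Gaussian smoothing of an impulse has the analytic second moment", {
  img <- matrix(0, 65, 65); img[33, 33] <- 1
  f <- compute_pixel_features(img, scales = 2)
  sm <- f[, , "gauss_2"]
  rr <- matrix(seq_len(65), 65, 65)
  second_moment <- sum(sm * (rr - 33)^2) / sum(sm)
  expect_equal(second_moment, 4, tolerance = 0.02) # sigma^2 = 4
})

test_that("a linearly separable two-class problem trains to 100% accuracy", {
  img <- matrix(10, 64, 64)
  img[, 33:64] <- 200
  lab <- matrix(0L, 64, 64)
  lab[5:25, 5:25] <- 1L     # dark
  lab[5:25, 40:60] <- 2L    # bright
  clf <- train_pixel_classifier(compute_pixel_features(img), lab, seed = 1)
  expect_equal(clf$train_accuracy, 1)
  p <- predict_probabilities(clf, img)
  sums <- p[, , 1] + p[, , 2]
  expect_equal(range(sums), c(1, 1), tolerance = 1e-9)
})

test_that("degenerate brush labels are rejected", {
  img <- matrix(runif(32 * 32), 32, 32)
  lab1 <- matrix(0L, 32, 32); lab1[1:10, 1:10] <- 1L
  expect_error(train_pixel_classifier(compute_pixel_features(img), lab1, seed = 1),
               "2 classes")
  lab2 <- lab1; lab2[1, 11:14] <- 2L # only 4 px in class 2
  expect_error(train_pixel_classifier(compute_pixel_features(img), lab2, seed = 1),
               ">= 50")
})

test_that("predict_mask enforces the probability floor and minimum object size", {
  img <- matrix(10, 64, 64)
  img <- add_disc(img, c(20, 20), 6, 200)  # 113 px object
  img <- add_disc(img, c(50, 50), 2, 200)  # 13 px object
  lab <- auto_brush_labels(img, fg_quantile = 0.97, bg_quantile = 0.5)
  clf <- train_pixel_classifier(compute_pixel_features(img), lab, seed = 1)
  m <- predict_mask(clf, img, p_min = 0.5, min_object_px = 20L)
  comp <- EBImage::bwlabel(m * 1)
  areas <- tabulate(comp[comp > 0])
  expect_true(all(areas >= 20))
  expect_equal(max(comp), 1) # the 13-px object was filtered out
  expect_true(all(!predict_mask(clf, img, p_min = 1, min_object_px = 1e6)))
  expect_error(predict_mask(clf, img, class_name = "nope"), "unknown class")
})

test_that("classifier masks are deterministic for a fixed seed", {
  sc <- small_scene()
  img <- sc$cycles[[1]]$IBA1
  lab <- auto_brush_labels(img, seed = 3)
  f <- compute_pixel_features(img)
  m1 <- predict_mask(train_pixel_classifier(f, lab, seed = 9), img)
  m2 <- predict_mask(train_pixel_classifier(f, lab, seed = 9), img)
  expect_identical(m1, m2)
})

test_that("nucleus identification finds disjoint discs with accurate centroids", {
  img <- matrix(0, 128, 128)
  img <- add_disc(img, c(40, 40), 8, 100)
  img <- add_disc(img, c(40, 100), 8, 100)
  lab <- identify_nuclei(img, threshold = 50, size_range = c(20, 1000))
  expect_equal(max(lab), 2)
  cent <- cycloplex:::label_centroids(lab)
  cent <- cent[order(cent[, 2]), ]
  expect_lt(max(abs(cent - rbind(c(40, 40), c(40, 100)))), 1)
})

test_that("touching nuclei are split by the distance-transform watershed", {
  img <- matrix(0, 96, 96)
  img <- add_disc(img, c(48, 42), 8, 100)
  img <- add_disc(img, c(48, 54), 8, 100) # centers 12 px apart, radius 8: overlap
  split_lab <- identify_nuclei(img, threshold = 50, size_range = c(20, 1000), split = TRUE)
  merged_lab <- identify_nuclei(img, threshold = 50, size_range = c(20, 1000), split = FALSE)
  expect_equal(max(split_lab), 2)
  expect_equal(max(merged_lab), 1)
})

test_that("blank images give zero objects with a warning, labels stay contiguous", {
  expect_warning(lab <- identify_nuclei(matrix(0, 32, 32), threshold = 10), "empty")
  expect_equal(max(lab), 0)
  sc <- small_scene()
  nuc <- identify_nuclei(sc$cycles[[1]]$DAPI)
  expect_equal(sort(unique(as.vector(nuc[nuc > 0]))), seq_len(max(nuc)))
  # object count within 5% of truth at this spacing
  expect_lt(abs(max(nuc) - nrow(sc$gt$centers)) / nrow(sc$gt$centers), 0.05)
})

test_that("assemble_cells honors footprints, coverage and empty inputs", {
  nuclei <- matrix(0L, 64, 64)
  nuclei <- add_disc(nuclei, c(20, 20), 4, 1L)
  nuclei <- add_disc(nuclei, c(45, 45), 4, 2L)
  full_mask <- matrix(FALSE, 64, 64)
  full_mask <- add_disc(full_mask, c(20, 20), 10, TRUE)
  tab0 <- assemble_cells(nuclei)
  expect_equal(nrow(tab0), 2)
  expect_equal(grep("^pos_", names(tab0)), integer(0))
  tab <- assemble_cells(nuclei, marker_masks = list(M = full_mask),
                        marker_images = list(M = full_mask * 80),
                        coverage_min = 1)
  expect_true(tab$pos_M[1])   # nucleus 1 fully inside the mask
  expect_false(tab$pos_M[2])
  expect_gt(tab$mean_M[1], tab$mean_M[2])
  expect_error(assemble_cells(nuclei, marker_masks = list(M = matrix(FALSE, 10, 10))),
               "frame")
})

test_that("per-marker positivity matches simulated expression for nearly all cells", {
  sc <- small_scene()
  pp <- preprocess_cycles(sc$cycles, sc$panel, bg_radius_px = 30)
  nuc <- identify_nuclei(pp$cycles[[1]]$DAPI)
  masks <- list(); imgs <- list()
  for (i in seq_along(pp$cycles)) {
    for (m in setdiff(names(pp$cycles[[i]]), "DAPI")) {
      img <- pp$cycles[[i]][[m]]
      imgs[[m]] <- img
      clf <- train_pixel_classifier(compute_pixel_features(img),
                                    auto_brush_labels(img, seed = 1), seed = 1)
      masks[[m]] <- predict_mask(clf, img)
    }
  }
  tab <- assemble_cells(nuc, masks, imgs, nuclear_markers = "PCNA")
  # match each found cell to the nearest true cell
  d <- as.matrix(dist(rbind(cbind(tab$centroid_row, tab$centroid_col), sc$gt$centers)))
  n_found <- nrow(tab)
  match_idx <- apply(d[seq_len(n_found), -seq_len(n_found), drop = FALSE], 1, which.min)
  for (m in c("IBA1", "CLEC4F", "CK19")) {
    truth <- sc$gt$amplitudes[match_idx, m] > 0
    expect_gte(mean(tab[[paste0("pos_", m)]] == truth), 0.95)
  }
})
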