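test_that("density maps conserve mass for any point configuration", {
  # no points
  d0 <- density_map(matrix(numeric(0), 0, 2), c(200, 200), 20, 4)
  expect_equal(sum(d0$map), 0)
  expect_equal(d0$total_count, 0)
  # single point near a border still integrates to exactly 1
  d1 <- density_map(cbind(2, 3), c(200, 200), 25, 4)
  expect_equal(sum(d1$map), 1, tolerance = 1e-6)
  # many random points including border-adjacent ones
  set.seed(4)
  pts <- cbind(runif(300, 1, 200), runif(300, 1, 200))
  dm <- density_map(pts, c(200, 200), 15, 4)
  expect_equal(sum(dm$map), 300, tolerance = 1e-6)
  expect_true(all(dm$map >= 0))
  expect_error(density_map(cbind(500, 5), c(200, 200), 10, 4), "outside")
})

test_that("two well-separated clusters each hold their own mass", {
  set.seed(7)
  c1 <- cbind(runif(50, 180, 220), runif(50, 180, 220))
  c2 <- cbind(runif(50, 580, 620), runif(50, 180, 220))
  dm <- density_map(rbind(c1, c2), c(800, 800), 20, 4)
  gr <- (seq_len(nrow(dm$map)) - 0.5) * dm$downsample
  gc <- (seq_len(ncol(dm$map)) - 0.5) * dm$downsample
  near1 <- outer((gr - 200)^2, (gc - 200)^2, `+`) <= 100^2
  near2 <- outer((gr - 600)^2, (gc - 200)^2, `+`) <= 100^2
  expect_equal(sum(dm$map[near1]), 50, tolerance = 0.02)
  expect_equal(sum(dm$map[near2]), 50, tolerance = 0.02)
})

test_that("neighbor_count at distance 0 keeps only centroids on reference pixels", {
  ref <- matrix(0L, 40, 40)
  ref[10:15, 10:15] <- 1L
  targets <- data.frame(centroid_row = c(12, 20), centroid_col = c(12, 20))
  nb <- neighbor_count(ref, targets, 0)
  expect_equal(nb$per_object$count, 1L)
  expect_equal(nb$total_unique, 1L)
})

test_that("a square reference counts targets by true Euclidean boundary distance", {
  ref <- matrix(0L, 100, 100)
  ref[40:59, 40:59] <- 1L # 20x20 square
  targets <- data.frame(centroid_row = c(50, 50), centroid_col = c(64, 74)) # 5 and 15 px out
  nb <- neighbor_count(ref, targets, 10)
  expect_equal(nb$per_object$count, 1L)
  nb_area <- neighbor_count(ref, targets, 10, tissue_area = 10000)
  expect_equal(nb_area$per_area, 1 / 10000)
  expect_error(neighbor_count(ref, targets, -1), ">= 0")
})

test_that("dilation-based counts equal the brute-force distance oracle on random fixtures", {
  for (case in 1:5) {
    set.seed(100 + case)
    ref <- matrix(0L, 120, 120)
    n_obj <- sample(3:10, 1)
    for (k in seq_len(n_obj))
      ref <- add_disc(ref, c(runif(1, 10, 110), runif(1, 10, 110)), runif(1, 2, 6), k)
    ref <- EBImage::imageData(EBImage::bwlabel(ref > 0)) # relabel after overlap
    targets <- data.frame(centroid_row = runif(60, 1, 120),
                          centroid_col = runif(60, 1, 120))
    for (r in c(0L, 6L, 10L)) {
      nb <- neighbor_count(ref, targets, r)
      oracle <- neighbor_count_oracle(ref, targets, r)
      expect_identical(nb$per_object$count, oracle$per_object)
      expect_identical(nb$total_unique, oracle$total_unique)
    }
  }
})

test_that("region delineation: empty collagen, missing nuclei, and threshold monotonicity", {
  blank <- matrix(FALSE, 64, 64)
  no_cells <- matrix(numeric(0), 0, 2)
  reg <- define_regions(blank, no_cells)
  expect_equal(reg$n_tumor, 0)
  expect_true(all(reg$labels == 1)) # a single extratumoral region
  # a closed ring with no PCNA nuclei inside is not a tumor
  ring <- add_disc(matrix(FALSE, 128, 128), c(64, 64), 40, TRUE) &
    !add_disc(matrix(FALSE, 128, 128), c(64, 64), 34, TRUE)
  reg0 <- define_regions(ring, no_cells, min_region_px = 100)
  expect_equal(reg0$n_tumor, 0)
  # with 20 nuclei inside it is
  inside <- cbind(runif(20, 50, 78), runif(20, 50, 78))
  reg1 <- define_regions(ring, inside, min_pcna_nuclei = 10, min_region_px = 100)
  expect_equal(reg1$n_tumor, 1)
  # raising min_pcna_nuclei can only lose regions
  reg2 <- define_regions(ring, inside, min_pcna_nuclei = 21, min_region_px = 100)
  expect_lte(reg2$n_tumor, reg1$n_tumor)
  expect_equal(reg2$n_tumor, 0)
})

test_that("a gapped capsule is sealed by closing up to the closing radius", {
  ring <- add_disc(matrix(FALSE, 128, 128), c(64, 64), 40, TRUE) &
    !add_disc(matrix(FALSE, 128, 128), c(64, 64), 34, TRUE)
  ring[62:66, ] <- ring[62:66, ] & (col(ring)[62:66, ] < 98) # cut a ~6 px gap
  inside <- cbind(runif(20, 50, 78), runif(20, 50, 78))
  open_reg <- define_regions(ring, inside, closing_px = 0, min_pcna_nuclei = 10,
                             min_region_px = 100)
  closed_reg <- define_regions(ring, inside, closing_px = 10, min_pcna_nuclei = 10,
                               min_region_px = 100)
  expect_equal(open_reg$n_tumor, 0)
  expect_equal(closed_reg$n_tumor, 1)
})

test_that("simulated tumors are recovered and composition conserves all cells", {
  sc <- tumor_scene()
  collagen <- extract_collagen(render_trichrome(sc$gt, sc$cfg))
  pcna_pos <- sc$gt$amplitudes[, "PCNA"] > 0
  reg <- define_regions(collagen, sc$gt$centers[pcna_pos, , drop = FALSE],
                        min_pcna_nuclei = 10)
  expect_gt(reg$n_tumor, 0)
  for (k in seq_len(reg$n_tumor)) {
    best <- max(vapply(seq_len(max(sc$gt$region_mask)), function(j)
      jaccard(reg$labels == k, sc$gt$region_mask == j), numeric(1)))
    expect_gte(best, 0.9)
  }
  tab <- data.frame(centroid_row = sc$gt$centers[, 1],
                    centroid_col = sc$gt$centers[, 2],
                    phenotype = sc$gt$phenotype)
  comp <- region_composition(reg, tab)
  expect_equal(sum(comp$n_cells), nrow(tab))
  # per-phenotype totals over regions match the whole-table composition
  per_phen <- tapply(comp$n_cells, comp$phenotype, sum)
  phens <- sort(unique(tab$phenotype))
  expect_equal(as.numeric(per_phen[phens]),
               as.numeric(table(tab$phenotype)[phens]))
  # KCs are excluded from tumors by construction
  kc <- comp[comp$phenotype == "KC" & comp$class == "tumor", ]
  if (nrow(kc)) expect_true(all(kc$fraction_of_macrophages %in% c(0, NA) | kc$n_cells == 0))
})
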