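# Shared fixtures, computed once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Identity-transform list of a given length.
identity_transforms <- function(n) replicate(n, affine_identity(), simplify = FALSE)

# Small clean scene: 256^2, 40 cells, no misalignment, default noise.
small_scene <- function() fixture("small_scene", function() {
  cfg <- simulation_config(image_shape = c(256L, 256L), n_cells = 40L,
                           n_cycles = 3L, cycle_transforms = identity_transforms(3),
                           border_margin_px = 24, rng_seed = 11L)
  gt <- generate_ground_truth(cfg)
  panel <- default_panel(3L)
  list(cfg = cfg, gt = gt, panel = panel, cycles = render_cycles(gt, cfg, panel))
})

# Noiseless, background-free scene for exact-value checks.
clean_scene <- function() fixture("clean_scene", function() {
  cfg <- simulation_config(image_shape = c(256L, 256L), n_cells = 30L,
                           n_cycles = 3L, cycle_transforms = identity_transforms(3),
                           background = c(0, 0), af_amplitude = 0, noise_sd = 0,
                           border_margin_px = 24, rng_seed = 5L)
  gt <- generate_ground_truth(cfg)
  panel <- default_panel(3L)
  list(cfg = cfg, gt = gt, panel = panel, cycles = render_cycles(gt, cfg, panel))
})

# Tumor scenario scene at moderate scale.
tumor_scene <- function() fixture("tumor_scene", function() {
  cfg <- simulation_config(image_shape = c(512L, 512L), n_cells = 400L,
                           scenario = "tumor", n_tumors = 2L,
                           tumor_radius_range = c(60, 80),
                           cycle_transforms = identity_transforms(3),
                           rng_seed = 5L)
  gt <- generate_ground_truth(cfg)
  list(cfg = cfg, gt = gt)
})

# A hand-made cell table for gating / fraction tests.
toy_cell_table <- function(pos_IBA1, pos_CLEC4F, pos_CK19 = NULL, pos_PCNA = NULL) {
  n <- length(pos_IBA1)
  tab <- data.frame(cell_id = seq_len(n),
                    centroid_row = rep(5, n), centroid_col = rep(5, n),
                    area_px = rep(20L, n),
                    pos_IBA1 = pos_IBA1, pos_CLEC4F = pos_CLEC4F)
  if (!is.null(pos_CK19)) tab$pos_CK19 <- pos_CK19
  if (!is.null(pos_PCNA)) tab$pos_PCNA <- pos_PCNA
  tab
}

# Draw a filled disc into a matrix (1-based center).
add_disc <- function(m, center, radius, value = 1) {
  rr <- matrix(seq_len(nrow(m)), nrow(m), ncol(m))
  cc <- matrix(rep(seq_len(ncol(m)), each = nrow(m)), nrow(m), ncol(m))
  m[(rr - center[1])^2 + (cc - center[2])^2 <= radius^2] <- value
  m
}

# Brute-force neighbor counting oracle: a target counts for an object iff
# the Euclidean distance from its centroid pixel to any object pixel is
# <= radius (integer-exact via squared distances).
neighbor_count_oracle <- function(reference, targets, distance_px) {
  n_obj <- max(reference)
  cr <- pmin(pmax(round(targets$centroid_row), 1L), nrow(reference))
  cc <- pmin(pmax(round(targets$centroid_col), 1L), ncol(reference))
  counts <- integer(n_obj)
  counted <- rep(FALSE, nrow(targets))
  for (obj in seq_len(n_obj)) {
    idx <- which(reference == obj)
    orr <- (idx - 1L) %% nrow(reference) + 1L
    occ <- (idx - 1L) %/% nrow(reference) + 1L
    for (k in seq_len(nrow(targets))) {
      d2 <- (orr - cr[k])^2 + (occ - cc[k])^2
      if (min(d2) <= distance_px^2) {
        counts[obj] <- counts[obj] + 1L
        counted[k] <- TRUE
      }
    }
  }
  list(per_object = counts, total_unique = sum(counted))
}

# Mean displacement of true cell centers after mapping through the
# estimated transform, against their reference-frame positions.
landmark_error <- function(true_t, est_t, centers) {
  moving <- affine_apply(affine_invert(true_t), centers)
  back <- affine_apply(est_t, moving)
  mean(sqrt(rowSums((back - centers)^2)))
}

jaccard <- function(a, b) sum(a & b) / sum(a | b)
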