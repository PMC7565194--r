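#' Simulation configuration for synthetic tissue
#'
#' Defines the rendered scene: scattered cells with a minimum
#' center-to-center distance, phenotype frequencies, a per-phenotype /
#' per-marker expression model, per-cycle misalignments, a smooth
#' background plane, a shared autofluorescence (AF) component and
#' shot-like noise. Defaults emulate a liver-injury panel: Kupffer cells
#' (KC, IBA1+CLEC4F+), monocyte-derived macrophages (MoMF, IBA1+CLEC4F-),
#' ductular cells (CK19+) and marker-negative parenchyma, with nuclear
#' proliferation (PCNA) more frequent in the macrophage compartment.
#'
#' @param image_shape integer (rows, cols).
#' @param n_cells number of cells to place.
#' @param min_center_distance_px minimum pairwise center distance.
#' @param phenotype_frequencies named probabilities, summing to 1.
#' @param marker_model nested list: `model[[phenotype]][[marker]]` is
#'   `c(p, mean, sd)` — expression probability and amplitude moments.
#'   Defaults via [default_marker_model()].
#' @param nucleus_radius_px,cell_radius_px object radii; rendered spot
#'   sigma is half the radius.
#' @param dapi_mean,dapi_sd nuclear-channel amplitude moments (all cells).
#' @param n_cycles number of staining cycles.
#' @param cycle_transforms optional list of true `affine_transform`s
#'   (cycle frame -> reference frame), cycle 0 identity; if `NULL`, drawn
#'   uniformly within `max_translation_px` / `max_rotation_deg` /
#'   `scale_range`.
#' @param max_translation_px,max_rotation_deg,scale_range bounds for
#'   drawn misalignments.
#' @param background `c(offset, slope)` — constant plus linear gradient.
#' @param af_amplitude peak of the smooth shared AF field.
#' @param af_mix named per-marker AF mixing coefficients (defaults: 0.3
#'   for every non-nuclear marker, 0 for the nuclear channel).
#' @param noise_sd noise scale; additive Gaussian with
#'   `sd = noise_sd * sqrt(intensity)`, clipped at 0.
#' @param border_margin_px keep-out border so cells stay in frame across
#'   misaligned cycles.
#' @param scenario `"plain"`, or `"tumor"` to add collagen-ring
#'   encapsulated regions with elevated PCNA positivity inside and KC
#'   exclusion.
#' @param n_tumors,tumor_radius_range,ring_thickness_px,pcna_inside
#'   tumor-scenario geometry and the PCNA expression probability inside.
#' @param rng_seed integer seed; the same seed gives bit-identical
#'   ground truth and rendered images.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(image_shape = c(1024L, 1024L),
                              n_cells = 300L,
                              min_center_distance_px = 12,
                              phenotype_frequencies = c(KC = 0.3, MoMF = 0.3,
                                                        ductular = 0.1, other = 0.3),
                              marker_model = NULL,
                              nucleus_radius_px = 4,
                              cell_radius_px = 7,
                              dapi_mean = 200, dapi_sd = 20,
                              n_cycles = 3L,
                              cycle_transforms = NULL,
                              max_translation_px = 20,
                              max_rotation_deg = 3,
                              scale_range = c(0.98, 1.02),
                              background = c(offset = 10, slope = 0.005),
                              af_amplitude = 20,
                              af_mix = NULL,
                              noise_sd = 0.5,
                              border_margin_px = 40,
                              scenario = c("plain", "tumor"),
                              n_tumors = 3L,
                              tumor_radius_range = c(70, 110),
                              ring_thickness_px = 6,
                              pcna_inside = 0.6,
                              rng_seed = 1L) {
  scenario <- match.arg(scenario)
  if (abs(sum(phenotype_frequencies) - 1) > 1e-9)
    stop_config("phenotype frequencies must sum to 1")
  if (cell_radius_px < nucleus_radius_px)
    stop_config("cell_radius_px must be >= nucleus_radius_px")
  if (min_center_distance_px < 2 * nucleus_radius_px)
    stop_config("min_center_distance_px must be >= 2 * nucleus_radius_px")
  if (is.null(marker_model))
    marker_model <- default_marker_model(names(phenotype_frequencies))
  markers <- unique(unlist(lapply(marker_model, names)))
  if (is.null(af_mix)) af_mix <- setNames(rep(0.3, length(markers)), markers)
  structure(list(image_shape = as.integer(image_shape), n_cells = as.integer(n_cells),
                 min_center_distance_px = min_center_distance_px,
                 phenotype_frequencies = phenotype_frequencies,
                 marker_model = marker_model, markers = markers,
                 nucleus_radius_px = nucleus_radius_px, cell_radius_px = cell_radius_px,
                 dapi_mean = dapi_mean, dapi_sd = dapi_sd,
                 n_cycles = as.integer(n_cycles), cycle_transforms = cycle_transforms,
                 max_translation_px = max_translation_px,
                 max_rotation_deg = max_rotation_deg, scale_range = scale_range,
                 background = background, af_amplitude = af_amplitude,
                 af_mix = af_mix, noise_sd = noise_sd,
                 border_margin_px = border_margin_px,
                 scenario = scenario, n_tumors = as.integer(n_tumors),
                 tumor_radius_range = tumor_radius_range,
                 ring_thickness_px = ring_thickness_px, pcna_inside = pcna_inside,
                 rng_seed = as.integer(rng_seed)),
            class = "simulation_config")
}

#' Default per-phenotype marker expression model
#'
#' Expression amplitudes are `c(p, mean, sd)`: a cell expresses the
#' marker with probability `p`, with amplitude `max(0, N(mean, sd))`.
#' KC express IBA1 and CLEC4F, MoMF IBA1 only, ductular cells CK19;
#' PCNA positivity is 0.3 in the IBA1+ compartment and 0.05 elsewhere.
#'
#' @param phenotypes phenotype labels to include.
#' @export
default_marker_model <- function(phenotypes = c("KC", "MoMF", "ductular", "other")) {
  on <- c(p = 1, mean = 150, sd = 20)
  off <- c(p = 0, mean = 0, sd = 0)
  pcna_hi <- c(p = 0.3, mean = 150, sd = 20)
  pcna_lo <- c(p = 0.05, mean = 150, sd = 20)
  full <- list(
    KC = list(IBA1 = on, CLEC4F = on, CK19 = off, PCNA = pcna_hi),
    MoMF = list(IBA1 = on, CLEC4F = off, CK19 = off, PCNA = pcna_hi),
    ductular = list(IBA1 = off, CLEC4F = off, CK19 = on, PCNA = pcna_lo),
    other = list(IBA1 = off, CLEC4F = off, CK19 = off, PCNA = pcna_lo)
  )
  missing <- setdiff(phenotypes, names(full))
  for (m in missing) full[[m]] <- list(IBA1 = off, CLEC4F = off, CK19 = off, PCNA = pcna_lo)
  full[phenotypes]
}

#' Default panel matching the simulator's marker model
#'
#' Three informative cycles (DAPI+IBA1; DAPI+CLEC4F+CK19; DAPI+PCNA);
#' further cycles carry DAPI only. Gating rules follow the liver
#' macrophage convention: KC = IBA1+CLEC4F+, MoMF = IBA1+CLEC4F-,
#' ductular = CK19+.
#'
#' @param n_cycles number of cycles (>= 3 recommended).
#' @export
default_panel <- function(n_cycles = 3L) {
  cycles <- list(c(c1 = "DAPI", c2 = "IBA1"),
                 c(c1 = "DAPI", c2 = "CLEC4F", c3 = "CK19"),
                 c(c1 = "DAPI", c2 = "PCNA"))
  if (n_cycles < 3L) cycles <- cycles[seq_len(n_cycles)]
  while (length(cycles) < n_cycles) cycles <- c(cycles, list(c(c1 = "DAPI")))
  gating <- list(list(phenotype = "KC", require = c("IBA1+", "CLEC4F+"), priority = 1),
                 list(phenotype = "MoMF", require = c("IBA1+", "CLEC4F-"), priority = 2),
                 list(phenotype = "ductular", require = c("CK19+"), priority = 3))
  panel_config(cycles = cycles, nuclear_channel = "DAPI",
               gating = if (n_cycles >= 3L) gating else list())
}

#' Generate ground truth for a synthetic tissue scene
#'
#' Places `n_cells` centers by dart throwing with minimum-distance
#' rejection, samples phenotypes i.i.d. from the configured frequencies,
#' draws per-marker amplitudes from the expression model (truncated at
#' 0), draws per-cycle misalignments, and builds the shared AF field and
#' (in the tumor scenario) the collagen rings and true region mask.
#'
#' @param config a [simulation_config()].
#' @param max_attempts_per_cell dart-throwing retry budget; exceeding it
#'   raises a capacity error.
#' @return A `ground_truth` list: `centers` (n x 2, 1-based), `phenotype`,
#'   `amplitudes` (n x markers, includes DAPI), `cycle_transforms`,
#'   `af_image`, and for tumor scenarios `collagen_mask` / `region_mask`.
#' @export
generate_ground_truth <- function(config, max_attempts_per_cell = 200L) {
  # Each stochastic component draws from its own sub-seed so that any one
  # of them (e.g. the phenotype multinomial) can be re-drawn independently.
  seed0 <- config$rng_seed
  local({
    sh <- config$image_shape
    margin <- config$border_margin_px
    if (2 * margin >= min(sh)) stop_config("border margin too large for image")

    tumors <- NULL
    if (config$scenario == "tumor")
      tumors <- with_seed(seed0 + 29L, draw_tumors(config))

    centers <- with_seed(seed0 + 11L,
      place_centers(config$n_cells, sh, margin,
                    config$min_center_distance_px, max_attempts_per_cell))
    phen <- character(0)
    if (config$n_cells > 0)
      phen <- with_seed(seed0 + 13L,
        sample(names(config$phenotype_frequencies), config$n_cells,
               replace = TRUE, prob = config$phenotype_frequencies))

    # Tumor scenario: KCs are excluded from tumor disks (resampled outside).
    if (!is.null(tumors) && config$n_cells > 0) with_seed(seed0 + 31L, {
      inside <- in_any_tumor(centers, tumors)
      bad <- which(phen == "KC" & inside)
      for (i in bad) {
        for (a in seq_len(max_attempts_per_cell)) {
          cand <- c(runif(1, 1 + margin, sh[1] - margin),
                    runif(1, 1 + margin, sh[2] - margin))
          d2 <- (centers[-i, 1] - cand[1])^2 + (centers[-i, 2] - cand[2])^2
          if ((nrow(centers) == 1 || min(d2) >= config$min_center_distance_px^2) &&
              !in_any_tumor(matrix(cand, 1), tumors)) {
            centers[i, ] <- cand
            break
          }
          if (a == max_attempts_per_cell)
            stop_input("cannot relocate Kupffer cell outside tumor regions")
        }
      }
    })

    amps <- with_seed(seed0 + 17L, draw_amplitudes(config, phen, centers, tumors))
    transforms <- config$cycle_transforms %||% with_seed(seed0 + 19L, draw_transforms(config))
    af <- with_seed(seed0 + 23L, smooth_af_field(sh, config$af_amplitude))

    collagen <- matrix(FALSE, sh[1], sh[2])
    region <- matrix(0L, sh[1], sh[2])
    if (!is.null(tumors)) {
      masks <- tumor_masks(tumors, sh, config$ring_thickness_px)
      collagen <- masks$collagen
      region <- masks$region
    }

    structure(list(centers = centers, phenotype = phen, amplitudes = amps,
                   cycle_transforms = transforms, af_image = af,
                   collagen_mask = collagen, region_mask = region,
                   tumors = tumors, config = config),
              class = "ground_truth")
  })
}

place_centers <- function(n, shape, margin, min_dist, max_attempts_per_cell) {
  centers <- matrix(numeric(0), 0, 2)
  if (n == 0) return(centers)
  centers <- matrix(NA_real_, n, 2)
  d2min <- min_dist^2
  k <- 0L
  for (i in seq_len(n)) {
    placed <- FALSE
    for (a in seq_len(max_attempts_per_cell)) {
      cand <- c(runif(1, 1 + margin, shape[1] - margin),
                runif(1, 1 + margin, shape[2] - margin))
      if (k == 0L) { placed <- TRUE }
      else {
        d2 <- (centers[seq_len(k), 1] - cand[1])^2 + (centers[seq_len(k), 2] - cand[2])^2
        placed <- min(d2) >= d2min
      }
      if (placed) { k <- k + 1L; centers[k, ] <- cand; break }
    }
    if (!placed)
      stop_input("cannot place ", n, " cells at min distance ", min_dist,
                 " (capacity exceeded after ", max_attempts_per_cell, " attempts)")
  }
  centers
}

draw_amplitudes <- function(config, phen, centers, tumors) {
  n <- length(phen)
  markers <- c("DAPI", config$markers)
  amps <- matrix(0, n, length(markers), dimnames = list(NULL, markers))
  if (n == 0) return(amps)
  amps[, "DAPI"] <- pmax(0, rnorm(n, config$dapi_mean, config$dapi_sd))
  inside <- if (!is.null(tumors)) in_any_tumor(centers, tumors) else rep(FALSE, n)
  for (m in config$markers) {
    p <- vapply(phen, function(ph) config$marker_model[[ph]][[m]][["p"]], numeric(1))
    mu <- vapply(phen, function(ph) config$marker_model[[ph]][[m]][["mean"]], numeric(1))
    s <- vapply(phen, function(ph) config$marker_model[[ph]][[m]][["sd"]], numeric(1))
    if (m == "PCNA" && !is.null(tumors)) {
      # inside an encapsulated region every cell is proliferation-prone
      p[inside] <- config$pcna_inside
      mu[inside] <- pmax(mu[inside], 150); s[inside] <- pmax(s[inside], 20)
    }
    expr <- rbinom(n, 1, p) == 1
    amps[expr, m] <- pmax(0, rnorm(sum(expr), mu[expr], s[expr]))
  }
  amps
}

draw_transforms <- function(config) {
  sh <- config$image_shape
  center <- (1 + sh) / 2
  out <- vector("list", config$n_cycles)
  out[[1]] <- affine_identity()
  if (config$n_cycles > 1) {
    for (i in 2:config$n_cycles) {
      tr <- runif(2, -config$max_translation_px, config$max_translation_px)
      rot <- runif(1, -config$max_rotation_deg, config$max_rotation_deg)
      sc <- runif(1, config$scale_range[1], config$scale_range[2])
      out[[i]] <- affine_from_params(rotation_deg = rot, scale = sc,
                                     translation = tr, center = center)
    }
  }
  out
}

smooth_af_field <- function(shape, amplitude) {
  if (amplitude <= 0) return(matrix(0, shape[1], shape[2]))
  ng <- 12L
  coarse <- matrix(abs(rnorm(ng * ng)), ng, ng)
  rr <- seq(1, ng, length.out = shape[1])
  cc <- seq(1, ng, length.out = shape[2])
  up <- bilinear_sample(coarse, rep(rr, times = shape[2]), rep(cc, each = shape[1]))
  up <- matrix(up, shape[1], shape[2])
  up <- EBImage::imageData(EBImage::gblur(up, sigma = min(shape) / 40))
  up <- up - min(up)
  up * (amplitude / max(up))
}

draw_tumors <- function(config) {
  sh <- config$image_shape
  rmax <- config$tumor_radius_range[2]
  margin <- rmax + config$ring_thickness_px + 5
  tum <- matrix(NA_real_, config$n_tumors, 3) # row, col, radius
  k <- 0L
  for (i in seq_len(config$n_tumors)) {
    for (a in seq_len(500L)) {
      cand <- c(runif(1, 1 + margin, sh[1] - margin),
                runif(1, 1 + margin, sh[2] - margin),
                runif(1, config$tumor_radius_range[1], rmax))
      ok <- TRUE
      if (k > 0) {
        d <- sqrt((tum[seq_len(k), 1] - cand[1])^2 + (tum[seq_len(k), 2] - cand[2])^2)
        ok <- all(d > tum[seq_len(k), 3] + cand[3] + 2 * config$ring_thickness_px + 10)
      }
      if (ok) { k <- k + 1L; tum[k, ] <- cand; break }
      if (a == 500L) stop_input("cannot place ", config$n_tumors, " non-overlapping tumors")
    }
  }
  tum
}

in_any_tumor <- function(centers, tumors) {
  inside <- rep(FALSE, nrow(centers))
  for (j in seq_len(nrow(tumors))) {
    d2 <- (centers[, 1] - tumors[j, 1])^2 + (centers[, 2] - tumors[j, 2])^2
    inside <- inside | d2 <= tumors[j, 3]^2
  }
  inside
}

tumor_masks <- function(tumors, shape, thickness) {
  collagen <- matrix(FALSE, shape[1], shape[2])
  region <- matrix(0L, shape[1], shape[2])
  rr <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cc <- matrix(rep(seq_len(shape[2]), each = shape[1]), shape[1], shape[2])
  for (j in seq_len(nrow(tumors))) {
    d2 <- (rr - tumors[j, 1])^2 + (cc - tumors[j, 2])^2
    outer_r <- tumors[j, 3]
    inner_r <- outer_r - thickness
    collagen <- collagen | (d2 <= outer_r^2 & d2 > inner_r^2)
    region[d2 <= inner_r^2] <- j
  }
  list(collagen = collagen, region = region)
}

#' Render the multi-cycle fluorescence images for a ground truth
#'
#' Each marker channel is the sum, over cells expressing the marker, of
#' an isotropic Gaussian spot (sigma = radius / 2, truncated at 4 sigma)
#' scaled by the cell's amplitude, plus the background plane and the
#' AF-mixed shared autofluorescence field. The nuclear channel renders
#' every cell. Channels are then warped into the cycle's own frame by
#' the cycle's true transform, and shot-like noise is added last.
#'
#' @param gt a `ground_truth`.
#' @param config the matching [simulation_config()].
#' @param panel a [panel_config()]; cycle layout must be consistent with
#'   the configured markers.
#' @return list of cycles, each a named list of channel matrices.
#' @export
render_cycles <- function(gt, config, panel) {
  sh <- config$image_shape
  if (length(panel$cycles) != config$n_cycles)
    stop_config("panel has ", length(panel$cycles), " cycles but config expects ", config$n_cycles)
  unknown <- setdiff(setdiff(panel$markers, panel$nuclear_channel), config$markers)
  if (length(unknown))
    stop_config("panel markers not in the simulation model: ", paste(unknown, collapse = ", "))

  bg <- background_plane(sh, config$background)
  scene <- list()
  for (m in c(panel$nuclear_channel, setdiff(panel$markers, panel$nuclear_channel))) {
    if (m == panel$nuclear_channel) {
      img <- render_spots(sh, gt$centers, gt$amplitudes[, "DAPI"],
                          config$nucleus_radius_px / 2)
      af_c <- 0
    } else {
      img <- render_spots(sh, gt$centers, gt$amplitudes[, m], config$cell_radius_px / 2)
      af_c <- config$af_mix[[m]] %||% 0
    }
    scene[[m]] <- img + bg + af_c * gt$af_image
  }

  out <- vector("list", config$n_cycles)
  for (i in seq_len(config$n_cycles)) {
    tr <- gt$cycle_transforms[[i]]
    markers <- cycle_markers(panel, i)
    chans <- setNames(vector("list", length(markers)), markers)
    for (j in seq_along(markers)) {
      img <- scene[[markers[j]]]
      if (i > 1L) img <- warp_image(img, affine_invert(tr))$image
      if (config$noise_sd > 0) {
        img <- with_seed(config$rng_seed + 7919L * i + 131L * j, {
          pmax(0, img + rnorm(length(img), 0, config$noise_sd * sqrt(pmax(img, 0))))
        })
        img <- matrix(img, sh[1], sh[2])
      }
      chans[[j]] <- img
    }
    out[[i]] <- chans
  }
  out
}

background_plane <- function(shape, background) {
  off <- background[[1]]; slope <- background[[2]]
  rr <- matrix(seq_len(shape[1]) - 1, shape[1], shape[2])
  cc <- matrix(rep(seq_len(shape[2]) - 1, each = shape[1]), shape[1], shape[2])
  off + slope * (rr + cc) / 2
}

# Sum of truncated Gaussian spots; vectorized per cell over a 4-sigma patch.
render_spots <- function(shape, centers, amplitudes, sigma) {
  img <- matrix(0, shape[1], shape[2])
  if (!nrow(centers)) return(img)
  w <- ceiling(4 * sigma)
  for (i in seq_len(nrow(centers))) {
    a <- amplitudes[i]
    if (a <= 0) next
    r0 <- max(1L, floor(centers[i, 1] - w)); r1 <- min(shape[1], ceiling(centers[i, 1] + w))
    c0 <- max(1L, floor(centers[i, 2] - w)); c1 <- min(shape[2], ceiling(centers[i, 2] + w))
    dr <- (r0:r1) - centers[i, 1]
    dc <- (c0:c1) - centers[i, 2]
    patch <- a * exp(-outer(dr^2, dc^2, `+`) / (2 * sigma^2))
    img[r0:r1, c0:c1] <- img[r0:r1, c0:c1] + patch
  }
  img
}

#' Render a trichrome-like RGB image
#'
#' Collagen pixels are rendered in a blue hue band, tissue (cell disks)
#' in pink, and background near-white with saturation below 0.1 — the
#' color structure that a Masson's-trichrome color-threshold extraction
#' expects.
#'
#' @param gt a `ground_truth` (carries the true collagen mask).
#' @param config the matching [simulation_config()].
#' @return H x W x 3 array in \[0, 1\].
#' @export
render_trichrome <- function(gt, config) {
  sh <- config$image_shape
  tissue <- matrix(FALSE, sh[1], sh[2])
  if (nrow(gt$centers)) {
    r <- config$cell_radius_px
    for (i in seq_len(nrow(gt$centers))) {
      r0 <- max(1L, floor(gt$centers[i, 1] - r)); r1 <- min(sh[1], ceiling(gt$centers[i, 1] + r))
      c0 <- max(1L, floor(gt$centers[i, 2] - r)); c1 <- min(sh[2], ceiling(gt$centers[i, 2] + r))
      dr <- (r0:r1) - gt$centers[i, 1]; dc <- (c0:c1) - gt$centers[i, 2]
      tissue[r0:r1, c0:c1] <- tissue[r0:r1, c0:c1] | (outer(dr^2, dc^2, `+`) <= r^2)
    }
  }
  col_bg <- c(0.97, 0.97, 0.97)   # near-white, saturation 0
  col_tis <- c(0.85, 0.55, 0.62)  # pink (red hue band)
  col_col <- c(0.24, 0.33, 0.80)  # blue band: hue ~0.64, sat 0.7, val 0.8
  rgb <- array(0, dim = c(sh[1], sh[2], 3))
  for (k in 1:3) {
    p <- matrix(col_bg[k], sh[1], sh[2])
    p[tissue] <- col_tis[k]
    p[gt$collagen_mask] <- col_col[k]
    rgb[, , k] <- p
  }
  rgb
}
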