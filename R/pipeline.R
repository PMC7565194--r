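#' Run configuration for the end-to-end pipeline
#'
#' @param cycle_paths character vector of per-cycle TIFF paths.
#' @param panel_path path to the YAML panel file.
#' @param out_dir output directory (created if needed).
#' @param seed integer seed controlling every stochastic component
#'   (classifier training, auto-labeling subsampling).
#' @param af_path optional TIFF with the autofluorescence reference.
#' @param trichrome_path optional trichrome RGB TIFF for collagen
#'   extraction and region delineation.
#' @param do_preprocess,do_registration,do_segmentation stage toggles.
#' @param do_regions delineate tumor regions (needs `trichrome_path`).
#' @param params named list of parameter overrides; recognized keys:
#'   `bg_radius_px`, `cell_expand_px`, `coverage_min`, `min_object_px`,
#'   `p_min`, `nucleus_size_range`, `proliferation_marker`,
#'   `density_bandwidth_px`, `density_downsample`, `closing_px`,
#'   `min_pcna_nuclei`, `min_region_px`, `neighbor_reference`,
#'   `neighbor_target`, `neighbor_distance_px`.
#' @return a `run_config` list.
#' @export
run_config <- function(cycle_paths, panel_path, out_dir, seed = 1L,
                       af_path = NULL, trichrome_path = NULL,
                       do_preprocess = TRUE, do_registration = TRUE,
                       do_segmentation = TRUE, do_regions = FALSE,
                       params = list()) {
  for (p in c(cycle_paths, panel_path, af_path, trichrome_path))
    if (!file.exists(p)) stop_config("input file not found: ", p)
  defaults <- list(bg_radius_px = 50L, cell_expand_px = 3L, coverage_min = 0.3,
                   min_object_px = 20L, p_min = 0.5,
                   nucleus_size_range = c(10L, 2000L),
                   proliferation_marker = "PCNA",
                   density_bandwidth_px = 20, density_downsample = 4L,
                   closing_px = 10L, min_pcna_nuclei = 10L, min_region_px = 500L,
                   neighbor_reference = NULL, neighbor_target = NULL,
                   neighbor_distance_px = NULL)
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown)) stop_config("unknown parameter override(s): ",
                                   paste(unknown, collapse = ", "))
  structure(list(cycle_paths = cycle_paths, panel_path = panel_path,
                 out_dir = out_dir, seed = as.integer(seed),
                 af_path = af_path, trichrome_path = trichrome_path,
                 do_preprocess = do_preprocess, do_registration = do_registration,
                 do_segmentation = do_segmentation, do_regions = do_regions,
                 params = modifyList(defaults, params)),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes preprocess -> register -> crop -> segment -> assemble ->
#' gate -> spatial on the configured inputs and persists every
#' intermediate as plain TIFF/CSV plus a machine-readable run manifest.
#' Fully deterministic for a fixed config and seed.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the main in-memory results
#'   (`cell_table`, `summary`, `transforms`, `regions`, paths of written
#'   artifacts in `$files`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  prm <- config$params
  manifest <- list(package = "cycloplex",
                   version = as.character(utils::packageVersion("cycloplex")),
                   seed = config$seed, params = prm, stages = list())
  files <- list()
  t_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    manifest$stages[[name]] <<- list(seconds = round(proc.time()[["elapsed"]] - t0, 3))
    res
  }

  panel <- t_stage("load_panel", load_panel(config$panel_path))
  cycles <- t_stage("read_images", read_cycle_images(config$cycle_paths, panel))
  message("loaded ", length(cycles), " cycle(s), ",
          length(panel$markers), " marker(s)")

  af_scales <- NULL
  if (config$do_preprocess) {
    af <- if (!is.null(config$af_path)) read_tiff_pages(config$af_path)[[1]] else NULL
    pp <- t_stage("preprocess",
                  preprocess_cycles(cycles, panel, bg_radius_px = prm$bg_radius_px, af = af))
    cycles <- pp$cycles
    af_scales <- pp$af_scales
    if (length(af_scales))
      message("AF scales: ", paste(names(af_scales), signif(unlist(af_scales), 3),
                                   sep = "=", collapse = ", "))
  }

  transforms <- NULL
  if (config$do_registration && length(cycles) > 1) {
    reg <- t_stage("register", align_experiment(cycles, panel))
    message("registration scores: ", paste(signif(reg$scores, 3), collapse = ", "))
    rect <- crop_common_region(reg$validity)
    cycles <- lapply(reg$cycles, function(ch) lapply(ch, crop_apply, rect = rect))
    transforms <- reg$transforms
    files$transforms <- file.path(config$out_dir, "transforms.csv")
    write_transforms(transforms, files$transforms)
    manifest$crop <- as.list(rect)
  }

  # persist aligned channels
  for (i in seq_along(cycles)) {
    f <- file.path(config$out_dir, sprintf("aligned_cycle_%02d.tif", i - 1L))
    write_image_tiff(cycles[[i]], f)
    files[[paste0("cycle_", i - 1L)]] <- f
  }

  result <- list(transforms = transforms, af_scales = af_scales, files = files)
  if (config$do_segmentation) {
    dapi <- cycles[[1]][[panel$nuclear_channel]]
    nuclei <- t_stage("segment_nuclei",
                      identify_nuclei(dapi, size_range = prm$nucleus_size_range))
    message("nuclei found: ", max(nuclei))

    markers <- panel_marker_order(panel)
    seg <- t_stage("segment_markers", {
      imgs <- list(); masks <- list()
      for (i in seq_along(cycles)) {
        for (m in intersect(names(cycles[[i]]), markers)) {
          img <- cycles[[i]][[m]]
          imgs[[m]] <- img
          lab <- auto_brush_labels(img, seed = config$seed)
          feats <- compute_pixel_features(img)
          clf <- train_pixel_classifier(feats, lab, seed = config$seed)
          masks[[m]] <- predict_mask(clf, img, p_min = prm$p_min,
                                     min_object_px = prm$min_object_px)
        }
      }
      list(imgs = imgs, masks = masks)
    })
    marker_imgs <- seg$imgs
    marker_masks <- seg$masks

    tab <- t_stage("assemble", assemble_cells(
      nuclei, marker_masks, marker_imgs,
      cell_expand_px = prm$cell_expand_px, coverage_min = prm$coverage_min,
      nuclear_markers = intersect(prm$proliferation_marker, markers)))
    tab <- t_stage("gate", apply_gates(tab, panel$gating))
    files$cell_table <- file.path(config$out_dir, "cell_table.csv")
    write_cell_table(tab, files$cell_table)

    summ <- population_summary(tab, prm$proliferation_marker)
    files$summary <- file.path(config$out_dir, "population_summary.csv")
    write.csv(summ, files$summary, row.names = FALSE)
    message("phenotypes: ", paste(summ$phenotype, summ$n_cells, sep = "=", collapse = ", "))

    density_files <- t_stage("spatial", {
      out <- list()
      for (p in unique(tab$phenotype)) {
        sel <- tab$phenotype == p
        dmap <- density_map(cbind(tab$centroid_row[sel], tab$centroid_col[sel]),
                            dim(dapi), prm$density_bandwidth_px, prm$density_downsample)
        f <- file.path(config$out_dir, paste0("density_", p, ".tif"))
        scale <- max(dmap$map, 1e-12)
        write_image_tiff(dmap$map / scale, f, bits = 32)
        jsonlite::write_json(list(scale = scale, total_count = dmap$total_count),
                             paste0(f, ".meta.json"), auto_unbox = TRUE, digits = NA)
        out[[paste0("density_", p)]] <- f
      }
      out
    })
    files <- c(files, density_files)

    if (!is.null(prm$neighbor_reference) && !is.null(prm$neighbor_distance_px)) {
      nb <- t_stage("neighbors", {
        ref_mask <- marker_masks[[prm$neighbor_reference]]
        ref_lab <- EBImage::imageData(EBImage::bwlabel(ref_mask * 1))
        tgt <- tab[tab[[paste0("pos_", prm$neighbor_target)]], , drop = FALSE]
        neighbor_count(ref_lab, tgt, prm$neighbor_distance_px,
                       tissue_area = prod(dim(dapi)))
      })
      files$neighbors <- file.path(config$out_dir, "neighbor_counts.csv")
      write.csv(nb$per_object, files$neighbors, row.names = FALSE)
      result$neighbors <- nb
    }

    regions <- NULL
    if (config$do_regions && !is.null(config$trichrome_path)) {
      regions <- t_stage("regions", {
        rgbp <- tiff::readTIFF(config$trichrome_path)
        collagen <- extract_collagen(rgbp)
        pcna_pos <- tab[tab[[paste0("pos_", prm$proliferation_marker)]], , drop = FALSE]
        reg <- define_regions(collagen,
                              cbind(pcna_pos$centroid_row, pcna_pos$centroid_col),
                              closing_px = prm$closing_px,
                              min_pcna_nuclei = prm$min_pcna_nuclei,
                              min_region_px = prm$min_region_px)
        tab$region <- reg$labels[cbind(pmin(pmax(round(tab$centroid_row), 1L), nrow(reg$labels)),
                                       pmin(pmax(round(tab$centroid_col), 1L), ncol(reg$labels)))]
        write_cell_table(tab, files$cell_table)
        f_lab <- file.path(config$out_dir, "region_labels.tif")
        write_label_tiff(reg$labels, f_lab)
        comp <- region_composition(reg, tab)
        f_comp <- file.path(config$out_dir, "region_composition.csv")
        write.csv(comp, f_comp, row.names = FALSE)
        list(mask = reg, composition = comp, table = tab,
             files = list(regions = f_lab, region_composition = f_comp))
      })
      tab <- regions$table
      files <- c(files, regions$files)
    }

    files$qc_dapi <- file.path(config$out_dir, "qc_dapi_nuclei.png")
    write_qc_png(dapi, files$qc_dapi, mask = nuclei > 0)

    result$cell_table <- tab
    result$summary <- summ
    result$nuclei <- nuclei
    result$marker_masks <- marker_masks
    result$regions <- regions
  }

  result$files <- files
  manifest$outputs <- lapply(files, identity)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(result)
}

#' Simulate a synthetic experiment bundle on disk
#'
#' Renders a full synthetic experiment and writes it in the exact layout
#' [run_pipeline()] consumes: per-cycle multi-page TIFFs, the panel
#' YAML, the AF reference, a trichrome RGB TIFF (tumor scenario), plus
#' ground-truth CSVs (cells, true transforms) for validation.
#'
#' @param config a [simulation_config()].
#' @param out_dir output directory.
#' @param panel optional [panel_config()]; defaults to
#'   [default_panel()] with the configured cycle count.
#' @return list with file paths (`cycles`, `panel`, `af`, `truth_cells`,
#'   `truth_transforms`, and for tumor scenarios `trichrome`,
#'   `truth_regions`) plus the in-memory `ground_truth`.
#' @export
simulate_bundle <- function(config, out_dir, panel = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(panel)) panel <- default_panel(config$n_cycles)
  gt <- generate_ground_truth(config)
  cycles <- render_cycles(gt, config, panel)

  paths <- list(cycles = character(config$n_cycles))
  for (i in seq_len(config$n_cycles)) {
    f <- file.path(out_dir, sprintf("cycle_%02d.tif", i - 1L))
    write_image_tiff(cycles[[i]], f)
    paths$cycles[i] <- f
  }
  paths$panel <- file.path(out_dir, "panel.yaml")
  write_panel(panel, paths$panel)
  paths$af <- file.path(out_dir, "af_reference.tif")
  write_image_tiff(gt$af_image, paths$af)

  truth <- data.frame(cell_id = seq_len(nrow(gt$centers)),
                      centroid_row = gt$centers[, 1] - 1,
                      centroid_col = gt$centers[, 2] - 1,
                      phenotype = gt$phenotype)
  for (m in colnames(gt$amplitudes)) truth[[paste0("amp_", m)]] <- gt$amplitudes[, m]
  paths$truth_cells <- file.path(out_dir, "truth_cells.csv")
  write.csv(truth, paths$truth_cells, row.names = FALSE)
  paths$truth_transforms <- file.path(out_dir, "truth_transforms.csv")
  write_transforms(gt$cycle_transforms, paths$truth_transforms)

  if (config$scenario == "tumor") {
    rgbp <- render_trichrome(gt, config)
    paths$trichrome <- file.path(out_dir, "trichrome.tif")
    tiff::writeTIFF(rgbp, paths$trichrome, bits.per.sample = 8L)
    paths$truth_regions <- file.path(out_dir, "truth_regions.tif")
    write_label_tiff(gt$region_mask, paths$truth_regions)
    paths$truth_collagen <- file.path(out_dir, "truth_collagen.tif")
    write_label_tiff(gt$collagen_mask * 1L, paths$truth_collagen)
  }
  paths$config <- file.path(out_dir, "sim_config.yaml")
  cfg_echo <- config[c("image_shape", "n_cells", "min_center_distance_px",
                       "nucleus_radius_px", "cell_radius_px", "n_cycles",
                       "noise_sd", "af_amplitude", "scenario", "rng_seed")]
  cfg_echo$phenotype_frequencies <- as.list(config$phenotype_frequencies)
  yaml::write_yaml(cfg_echo, paths$config)

  paths$ground_truth <- gt
  invisible(paths)
}
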