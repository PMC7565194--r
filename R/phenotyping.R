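#' Assign phenotypes to cells by boolean gating
#'
#' Each rule is a conjunction of signed marker terms (e.g. Kupffer cell
#' = IBA1+ AND CLEC4F+). Rules are evaluated in priority order (lower
#' first); a cell gets the first rule it satisfies, and cells matching
#' no rule are labeled `"other"`. The assignment is a partition: exactly
#' one label per cell.
#'
#' @param table cell table with `pos_<marker>` columns.
#' @param rules gating rules from a [panel_config()] (`panel$gating`),
#'   or a `panel_config` itself.
#' @return the table with a `phenotype` column.
#' @export
apply_gates <- function(table, rules) {
  if (inherits(rules, "panel_config")) rules <- rules$gating
  needed <- unique(unlist(lapply(rules, function(r) r$terms$marker)))
  missing <- setdiff(paste0("pos_", needed), names(table))
  if (length(missing))
    stop_config("cell table lacks positivity columns: ", paste(missing, collapse = ", "))
  phen <- rep("other", nrow(table))
  unassigned <- rep(TRUE, nrow(table))
  for (r in rules[order(vapply(rules, `[[`, numeric(1), "priority"))]) {
    ok <- rep(TRUE, nrow(table))
    for (k in seq_len(nrow(r$terms))) {
      col <- table[[paste0("pos_", r$terms$marker[k])]]
      ok <- ok & (if (r$terms$positive[k]) col else !col)
    }
    hit <- unassigned & ok
    phen[hit] <- r$phenotype
    unassigned <- unassigned & !hit
  }
  table$phenotype <- phen
  table
}

#' Fraction of proliferating cells in a population
#'
#' @param table cell table with positivity columns (and `phenotype` if
#'   gating labels are used).
#' @param population a phenotype label (matched against `phenotype`) or
#'   a logical vector selecting rows.
#' @param proliferation_marker marker name (default `"PCNA"`).
#' @return list with `fraction` (NaN with `undefined = TRUE` for an
#'   empty population), `n_positive`, `n_total`, `undefined`.
#' @export
proliferation_fraction <- function(table, population, proliferation_marker = "PCNA") {
  col <- paste0("pos_", proliferation_marker)
  if (!col %in% names(table))
    stop_config("proliferation marker column '", col, "' not in table")
  sel <- if (is.logical(population)) population
    else table$phenotype == population
  n <- sum(sel)
  npos <- sum(sel & table[[col]])
  list(fraction = if (n == 0) NaN else npos / n,
       n_positive = npos, n_total = n, undefined = n == 0)
}

#' Per-phenotype population summary
#'
#' One row per phenotype: cell count, fraction of all cells, fraction
#' positive for the proliferation marker, and mean marker intensities.
#'
#' @param table gated cell table.
#' @param proliferation_marker marker used for the proliferating
#'   fraction (skipped if absent).
#' @export
population_summary <- function(table, proliferation_marker = "PCNA") {
  phens <- unique(table$phenotype)
  mean_cols <- grep("^mean_", names(table), value = TRUE)
  has_prolif <- paste0("pos_", proliferation_marker) %in% names(table)
  rows <- lapply(phens, function(p) {
    sel <- table$phenotype == p
    out <- data.frame(phenotype = p, n_cells = sum(sel),
                      fraction_of_all = sum(sel) / nrow(table))
    out$pcna_positive_fraction <- if (has_prolif)
      proliferation_fraction(table, p, proliferation_marker)$fraction else NA_real_
    for (mc in mean_cols) out[[mc]] <- mean(table[[mc]][sel])
    out
  })
  do.call(rbind, rows)
}

#' Stained-area statistics
#'
#' Pixel areas of marker masks within a tissue mask, fractions of the
#' tissue area, and pairwise area ratios. Compound masks (e.g.
#' IBA1+CLEC4F- = A AND NOT B) can be formed with plain logical algebra
#' before calling.
#'
#' @param masks named list of logical matrices.
#' @param tissue_mask logical matrix; nonempty.
#' @return list with `areas` (named pixel counts), `fractions`, and
#'   `ratios` (matrix; `NaN` where the denominator is empty).
#' @export
stained_area_stats <- function(masks, tissue_mask) {
  if (!any(tissue_mask)) stop_input("tissue mask is empty")
  for (m in masks) if (!all(dim(m) == dim(tissue_mask)))
    stop_input("mask shapes differ from tissue mask")
  tissue_area <- sum(tissue_mask)
  areas <- vapply(masks, function(m) sum(m & tissue_mask), numeric(1))
  ratios <- outer(areas, areas, function(a, b) ifelse(b == 0, NaN, a / b))
  list(areas = areas, fractions = areas / tissue_area,
       tissue_area = tissue_area, ratios = ratios)
}

#' Per-cell intensity scatter with quadrant counts
#'
#' Returns the (x, y) mean-intensity pairs for two markers and the cell
#' counts per quadrant at the given thresholds (the dot-plot view of
#' marker co-expression).
#'
#' @param table cell table with `mean_<marker>` columns.
#' @param marker_x,marker_y marker names.
#' @param threshold_x,threshold_y quadrant thresholds.
#' @return list with `points` (data.frame x, y) and `quadrants` (named
#'   counts `pp, pn, np, nn`; x-sign first, "p" means > threshold).
#' @export
intensity_scatter <- function(table, marker_x, marker_y,
                              threshold_x = 0, threshold_y = 0) {
  cx <- paste0("mean_", marker_x); cy <- paste0("mean_", marker_y)
  if (!cx %in% names(table)) stop_param("unknown marker '", marker_x, "'")
  if (!cy %in% names(table)) stop_param("unknown marker '", marker_y, "'")
  x <- table[[cx]]; y <- table[[cy]]
  px <- x > threshold_x; py <- y > threshold_y
  quad <- c(pp = sum(px & py), pn = sum(px & !py),
            np = sum(!px & py), nn = sum(!px & !py))
  list(points = data.frame(x = x, y = y), quadrants = quad)
}
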