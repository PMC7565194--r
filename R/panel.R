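#' Panel and gating configuration
#'
#' A panel describes the staining experiment: the ordered cycles with
#' their channel -> marker assignment, the nuclear counterstain imaged in
#' every cycle (the registration anchor, typically DAPI), the boolean
#' gating rules that turn per-marker positivity into phenotypes, and
#' optional parameter overrides for downstream stages.
#'
#' The on-disk format is YAML:
#' ```yaml
#' nuclear_channel: DAPI
#' cycles:
#'   - {c1: DAPI, c2: IBA1}
#'   - {c1: DAPI, c2: CLEC4F, c3: CK19}
#' gating:
#'   - {phenotype: KC,   require: [IBA1+, CLEC4F+], priority: 1}
#'   - {phenotype: MoMF, require: [IBA1+, CLEC4F-], priority: 2}
#' params: {cell_expand_px: 3}
#' ```
#' Gating rules are conjunctions of signed marker terms; rules are
#' evaluated in priority order (lower first) and the first match wins.
#' Unknown top-level keys are rejected so typos do not silently change a
#' run.
#'
#' @param path path to a YAML panel file.
#' @return A validated `panel_config` object.
#' @export
load_panel <- function(path) {
  if (!file.exists(path)) stop_input("panel file not found: ", path)
  raw <- yaml::read_yaml(path)
  panel_config(cycles = raw$cycles,
               nuclear_channel = raw$nuclear_channel,
               gating = raw$gating,
               params = raw$params,
               .extra_keys = setdiff(names(raw), c("cycles", "nuclear_channel", "gating", "params")))
}

#' Construct and validate a panel configuration
#'
#' @param cycles list of cycles; each cycle is a named list mapping
#'   channel name -> marker name, in acquisition order.
#' @param nuclear_channel marker name of the nuclear counterstain,
#'   present in every cycle.
#' @param gating list of rules, each a list with `phenotype`, `require`
#'   (character vector of `"MARKER+"` / `"MARKER-"` terms) and optional
#'   `priority`.
#' @param params named list of parameter overrides.
#' @param .extra_keys internal; unknown file keys to report.
#' @export
panel_config <- function(cycles, nuclear_channel, gating = list(),
                         params = list(), .extra_keys = character()) {
  if (length(.extra_keys))
    stop_config("unknown panel keys: ", paste(.extra_keys, collapse = ", "))
  if (is.null(cycles) || !length(cycles)) stop_config("panel must define at least one cycle")
  if (is.null(nuclear_channel) || !nzchar(nuclear_channel))
    stop_config("panel must name a nuclear_channel")
  cycles <- lapply(cycles, function(cy) {
    if (is.null(names(cy)) || any(!nzchar(names(cy))))
      stop_config("each cycle must map channel names to marker names")
    vapply(cy, as.character, character(1))
  })
  for (i in seq_along(cycles)) {
    if (!nuclear_channel %in% cycles[[i]])
      stop_config("cycle ", i - 1L, " lacks the nuclear channel '", nuclear_channel, "'")
  }
  markers <- unlist(lapply(cycles, unname), use.names = FALSE)
  non_nuclear <- markers[markers != nuclear_channel]
  if (anyDuplicated(non_nuclear))
    stop_config("marker names must be unique across the experiment: ",
                paste(unique(non_nuclear[duplicated(non_nuclear)]), collapse = ", "))
  all_markers <- unique(markers)

  rules <- lapply(seq_along(gating), function(i) parse_gating_rule(gating[[i]], i))
  for (r in rules) {
    missing <- setdiff(r$terms$marker, all_markers)
    if (length(missing))
      stop_config("gating rule '", r$phenotype, "' references unknown marker(s): ",
                  paste(missing, collapse = ", "))
  }
  if (length(rules)) rules <- rules[order(vapply(rules, `[[`, numeric(1), "priority"))]

  structure(list(cycles = cycles, nuclear_channel = nuclear_channel,
                 gating = rules, params = params %||% list(),
                 markers = all_markers),
            class = "panel_config")
}

parse_gating_rule <- function(rule, idx) {
  if (is.null(rule$phenotype) || is.null(rule$require))
    stop_config("gating rule ", idx, " needs 'phenotype' and 'require'")
  terms <- as.character(rule$require)
  if (!length(terms)) stop_config("gating rule '", rule$phenotype, "' has no terms")
  sign <- substring(terms, nchar(terms))
  ok <- sign %in% c("+", "-")
  if (!all(ok))
    stop_config("gating terms must end in '+' or '-': ",
                paste(terms[!ok], collapse = ", "))
  marker <- substring(terms, 1, nchar(terms) - 1)
  if (anyDuplicated(marker))
    stop_config("gating rule '", rule$phenotype, "' repeats marker ",
                paste(unique(marker[duplicated(marker)]), collapse = ", "))
  list(phenotype = as.character(rule$phenotype),
       terms = data.frame(marker = marker, positive = sign == "+"),
       priority = as.numeric(rule$priority %||% idx))
}

#' Write a panel configuration to YAML
#' @param panel a `panel_config`.
#' @param path output path.
#' @export
write_panel <- function(panel, path) {
  out <- list(
    nuclear_channel = panel$nuclear_channel,
    cycles = lapply(panel$cycles, as.list),
    gating = lapply(panel$gating, function(r) {
      list(phenotype = r$phenotype,
           require = paste0(r$terms$marker, ifelse(r$terms$positive, "+", "-")),
           priority = r$priority)
    }),
    params = panel$params
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.panel_config <- function(x, ...) {
  cat("panel_config:", length(x$cycles), "cycle(s), nuclear channel", x$nuclear_channel, "\n")
  for (i in seq_along(x$cycles))
    cat("  cycle", i - 1L, ":", paste(names(x$cycles[[i]]), x$cycles[[i]], sep = "=", collapse = ", "), "\n")
  for (r in x$gating)
    cat("  rule", r$phenotype, ":",
        paste0(r$terms$marker, ifelse(r$terms$positive, "+", "-"), collapse = " & "),
        "(priority", paste0(r$priority, ")"), "\n")
  invisible(x)
}

# Markers of one cycle in channel order.
cycle_markers <- function(panel, cycle_idx) unname(panel$cycles[[cycle_idx]])

# Panel-wide marker order excluding the nuclear channel.
panel_marker_order <- function(panel) setdiff(panel$markers, panel$nuclear_channel)
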