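#' Styling configuration for SVG metabolic maps
#'
#' Colors follow the convention of enrichment maps: orange for reactions
#' upregulated in the first group, sky blue for downregulated, red/blue for
#' reversible reactions whose flux direction flips between groups, light
#' grey for non-significant arrows. `id_pattern` locates a reaction's arrow
#' element in the SVG by element id; the default `"R_{reaction_id}"`
#' matches Escher-style exported maps.
#'
#' @param color_up,color_down,color_flip_up,color_flip_down,color_ns CSS
#'   color strings.
#' @param ramp_low,ramp_high endpoints of the sequential color ramp used by
#'   magnitude (mean/median) maps.
#' @param width_min,width_max stroke widths in SVG user units,
#'   `width_min < width_max`.
#' @param id_pattern template with a `{reaction_id}` placeholder.
#' @return list of class `map_style_config`.
#' @export
map_style_config <- function(color_up = "#FFA500", color_down = "#87CEEB",
                             color_flip_up = "#FF0000",
                             color_flip_down = "#0000FF",
                             color_ns = "#BEBEBE",
                             ramp_low = "#D9D9D9", ramp_high = "#B2182B",
                             width_min = 2, width_max = 12,
                             id_pattern = "R_{reaction_id}") {
  stopifnot(width_min < width_max, grepl("{reaction_id}", id_pattern, fixed = TRUE))
  structure(list(color_up = color_up, color_down = color_down,
                 color_flip_up = color_flip_up,
                 color_flip_down = color_flip_down, color_ns = color_ns,
                 ramp_low = ramp_low, ramp_high = ramp_high,
                 width_min = width_min, width_max = width_max,
                 id_pattern = id_pattern),
            class = "map_style_config")
}

read_svg_doc <- function(svg) {
  if (inherits(svg, "xml_document")) return(svg)
  tryCatch(xml2::read_xml(svg), error = function(e)
    stop("malformed SVG input: ", conditionMessage(e)))
}

map_element_index <- function(doc) {
  nodes <- xml2::xml_find_all(doc, "//*[@id]")
  ids <- xml2::xml_attr(nodes, "id")
  stats::setNames(as.list(nodes), ids)
}

# ids matching the pattern's literal prefix/suffix, with the reaction id
# extracted from the middle
pattern_parts <- function(id_pattern) {
  parts <- strsplit(id_pattern, "{reaction_id}", fixed = TRUE)[[1L]]
  list(prefix = parts[1L],
       suffix = if (length(parts) > 1L) parts[2L] else "")
}

ids_matching_pattern <- function(ids, id_pattern) {
  pp <- pattern_parts(id_pattern)
  ids <- setdiff(ids, "rasflux-legend")
  hit <- startsWith(ids, pp$prefix) & endsWith(ids, pp$suffix) &
    nchar(ids) > nchar(pp$prefix) + nchar(pp$suffix)
  rx <- substr(ids[hit], nchar(pp$prefix) + 1L,
               nchar(ids[hit]) - nchar(pp$suffix))
  stats::setNames(rx, ids[hit])
}

style_node <- function(node, color, width) {
  xml2::xml_set_attr(node, "stroke", color)
  xml2::xml_set_attr(node, "stroke-width", format(width, digits = 10))
  # stroke may also live in a style attribute; strip it there so the
  # explicit attributes win
  st <- xml2::xml_attr(node, "style")
  if (!is.na(st)) {
    st2 <- gsub("(stroke|stroke-width)\\s*:[^;]*;?", "", st)
    if (!identical(st, st2)) xml2::xml_set_attr(node, "style", st2)
  }
}

#' Paint group-comparison results onto an SVG metabolic map
#'
#' Each reaction arrow (element whose id matches
#' `id_pattern` with the reaction id substituted) gets a stroke color from
#' its style class and a stroke width
#' `width_min + (width_max - width_min) * |fold_change|` (the bounded
#' fold-change statistic, clamped to `[0, 1]`); non-significant arrows get
#' the neutral color at `width_min`. Elements not matched by any record
#' are left byte-identical; restyling with the same records is idempotent.
#' A small legend group (id `rasflux-legend`, replaced if already present)
#' is appended.
#'
#' @param svg SVG input: file path, SVG text, or an `xml2` document.
#' @param records one comparison data.frame from [compare_groups()].
#' @param config a [map_style_config()].
#' @return list of class `styled_map`: `doc` (the styled `xml_document`),
#'   `unmatched_map_ids` (arrow-like ids in the map with no record) and
#'   `unmatched_record_ids` (reactions in `records` absent from the map).
#' @export
style_comparison_map <- function(svg, records, config = map_style_config()) {
  doc <- read_svg_doc(svg)
  idx <- map_element_index(doc)
  matched <- character()
  colors <- c(up = config$color_up, down = config$color_down,
              sign_flip_up = config$color_flip_up,
              sign_flip_down = config$color_flip_down,
              not_significant = config$color_ns)
  for (i in seq_len(nrow(records))) {
    rid <- records$reaction_id[i]
    el_id <- sub("{reaction_id}", rid, config$id_pattern, fixed = TRUE)
    node <- idx[[el_id]]
    if (is.null(node)) next
    matched <- c(matched, rid)
    cls <- as.character(records$style_class[i])
    w <- if (cls == "not_significant") config$width_min
         else config$width_min + (config$width_max - config$width_min) *
              min(1, abs(records$fold_change[i]))
    style_node(node, unname(colors[[cls]]), w)
  }
  if (!length(matched))
    stop("no reaction id in the records matched any map element ",
         "(id pattern '", config$id_pattern, "')")

  map_rxns <- unname(ids_matching_pattern(names(idx), config$id_pattern))
  add_legend(doc, legend_entries_comparison(config))
  structure(list(doc = doc,
                 unmatched_map_ids = setdiff(map_rxns, records$reaction_id),
                 unmatched_record_ids = setdiff(records$reaction_id, map_rxns)),
            class = "styled_map")
}

#' Paint per-group flux magnitudes onto an SVG metabolic map
#'
#' Arrow width is linear in the absolute value of the chosen statistic,
#' rescaled so 0 maps to `width_min` and the largest magnitude maps to
#' `width_max` (all-zero summaries leave every arrow at `width_min`);
#' color follows a sequential ramp over the same rescaled magnitude.
#' Doubling every flux leaves the map unchanged (scale invariance). Flux
#' direction is not encoded: hand-drawn maps rarely carry paired
#' direction elements, so sign information is left to the comparison maps.
#'
#' @param svg SVG input as in [style_comparison_map()].
#' @param summary a [summarize_fluxes()] table.
#' @param statistic `"mean"` or `"median"`.
#' @param config a [map_style_config()].
#' @return A `styled_map` (see [style_comparison_map()]).
#' @export
style_magnitude_map <- function(svg, summary, statistic = c("mean", "median"),
                                config = map_style_config()) {
  statistic <- match.arg(statistic)
  doc <- read_svg_doc(svg)
  idx <- map_element_index(doc)
  vals <- abs(summary[[statistic]])
  mx <- max(vals)
  rel <- if (mx == 0) rep(0, length(vals)) else vals / mx
  ramp <- grDevices::colorRamp(c(config$ramp_low, config$ramp_high))
  matched <- character()
  for (i in seq_len(nrow(summary))) {
    el_id <- sub("{reaction_id}", summary$reaction_id[i], config$id_pattern,
                 fixed = TRUE)
    node <- idx[[el_id]]
    if (is.null(node)) next
    matched <- c(matched, summary$reaction_id[i])
    w <- config$width_min + (config$width_max - config$width_min) * rel[i]
    rgbv <- ramp(rel[i])
    style_node(node, grDevices::rgb(rgbv[1], rgbv[2], rgbv[3],
                                    maxColorValue = 255), w)
  }
  if (!length(matched))
    stop("no reaction id in the summary matched any map element ",
         "(id pattern '", config$id_pattern, "')")
  map_rxns <- unname(ids_matching_pattern(names(idx), config$id_pattern))
  add_legend(doc, legend_entries_magnitude(config, statistic))
  structure(list(doc = doc,
                 unmatched_map_ids = setdiff(map_rxns, summary$reaction_id),
                 unmatched_record_ids = setdiff(summary$reaction_id, map_rxns)),
            class = "styled_map")
}

legend_entries_comparison <- function(config) {
  list(c(config$color_up, "up in group 1"),
       c(config$color_down, "down in group 1"),
       c(config$color_flip_up, "direction flip (up)"),
       c(config$color_flip_down, "direction flip (down)"),
       c(config$color_ns, "not significant"))
}

legend_entries_magnitude <- function(config, statistic) {
  list(c(config$ramp_low, paste("low |", statistic, "| flux")),
       c(config$ramp_high, paste("high |", statistic, "| flux")))
}

add_legend <- function(doc, entries) {
  root <- xml2::xml_root(doc)
  old <- xml2::xml_find_first(root, ".//*[@id='rasflux-legend']")
  if (!inherits(old, "xml_missing")) xml2::xml_remove(old)
  g <- xml2::xml_add_child(root, "g", id = "rasflux-legend")
  y <- 12
  for (e in entries) {
    xml2::xml_add_child(g, "rect", x = "4", y = format(y - 8),
                        width = "10", height = "10", fill = e[1L])
    txt <- xml2::xml_add_child(g, "text", x = "18", y = format(y),
                               `font-size` = "9")
    xml2::xml_text(txt) <- e[2L]
    y <- y + 14
  }
  invisible(doc)
}

#' @export
print.styled_map <- function(x, ...) {
  cat(sprintf("styled_map: %d unmatched map id(s), %d unmatched record id(s)\n",
              length(x$unmatched_map_ids), length(x$unmatched_record_ids)))
  invisible(x)
}

#' Write a styled map (or any xml document) as SVG
#' @param x a `styled_map` or `xml_document`.
#' @param path output file path.
#' @export
write_svg <- function(x, path) {
  doc <- if (inherits(x, "styled_map")) x$doc else x
  xml2::write_xml(doc, path)
  invisible(path)
}
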