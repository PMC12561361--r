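# Glyph template serialization: JSON (canonical) and CSV (flat) formats.

#' Write glyph templates to JSON
#'
#' Canonical template format: an array of objects with `id` and `segments`,
#' each segment holding `label` and `points` (list of \[x, y\] pairs).
#' Coordinates are glyph units with x rightward and y upward; screen-down
#' sources must be flipped before import.
#'
#' @param templates a single [stroke_template()] or list of them.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_glyph_json <- function(templates, file) {
  if (inherits(templates, "stroke_template")) templates <- list(templates)
  payload <- lapply(templates, function(tp) {
    list(id = tp$id,
         segments = lapply(tp$segments, function(s)
           list(label = s$label, points = unname(s$points))))
  })
  jsonlite::write_json(unname(payload), file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Read glyph templates from JSON
#'
#' @param file path to a JSON file written by [write_glyph_json()] (or in
#'   the same schema). Connectivity of consecutive segments is validated.
#' @return list of [stroke_template()] objects.
#' @export
read_glyph_json <- function(file) {
  raw <- jsonlite::read_json(file, simplifyVector = FALSE)
  lapply(raw, function(tp) {
    if (is.null(tp$id) || is.null(tp$segments))
      stop("malformed glyph JSON: need 'id' and 'segments'")
    segs <- lapply(tp$segments, function(s) {
      pts <- do.call(rbind, lapply(s$points, function(p) as.numeric(unlist(p))))
      list(points = pts, label = s$label)
    })
    stroke_template(tp$id, segs)
  })
}

#' Write glyph templates to CSV
#'
#' Flat alternative to the JSON format: one row per polyline point with
#' columns `id`, `segment` (1-based index), `label`, `x`, `y`.
#'
#' @inheritParams write_glyph_json
#' @export
write_glyph_csv <- function(templates, file) {
  if (inherits(templates, "stroke_template")) templates <- list(templates)
  rows <- do.call(rbind, lapply(templates, function(tp) {
    do.call(rbind, lapply(seq_along(tp$segments), function(k) {
      s <- tp$segments[[k]]
      data.frame(id = tp$id, segment = k, label = s$label,
                 x = s$points[, 1L], y = s$points[, 2L])
    }))
  }))
  utils::write.csv(rows, file, row.names = FALSE)
  invisible(file)
}

#' Read glyph templates from CSV
#'
#' @param file path to a CSV written by [write_glyph_csv()].
#' @return list of [stroke_template()] objects.
#' @export
read_glyph_csv <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("id", "segment", "label", "x", "y")
  if (!all(need %in% names(df)))
    stop("malformed glyph CSV: need columns ", paste(need, collapse = ", "))
  lapply(split(df, factor(df$id, levels = unique(df$id))), function(g) {
    segs <- lapply(split(g, g$segment), function(s)
      list(points = cbind(s$x, s$y), label = s$label[1L]))
    stroke_template(g$id[1L], unname(segs))
  })
}
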