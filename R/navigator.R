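#' Read a SerialEM Navigator file (autodoc format)
#'
#' Parses the autodoc text format used by SerialEM Navigator version 2
#' files: an optional preamble (e.g. `AdocVersion = 2.00`) followed by
#' `[Item = label]` sections of `key = value` lines. Every line is kept
#' verbatim, so writing a document back ([write_navigator()]) reproduces
#' the input byte-for-byte up to line-ending normalization, and keys this
#' package does not interpret survive untouched — the file stays usable
#' by the acquisition software.
#'
#' @param path Path to a `.nav` file.
#' @return A `navigator_document`: list with `preamble` (character
#'   vector) and `items`, each item a list of `label`, `lines` (verbatim,
#'   including the section header) and `kv` (named character vector of
#'   parsed keys).
#' @export
read_navigator <- function(path) {
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  hdr <- grep("^\\s*\\[", lines)
  bad <- hdr[!grepl("^\\s*\\[\\s*Item\\s*=\\s*[^]]+\\]\\s*$", lines[hdr])]
  if (length(bad)) {
    stop("malformed section header at line ", bad[1L], ": '",
         lines[bad[1L]], "'")
  }
  preamble <- if (length(hdr)) lines[seq_len(hdr[1L] - 1L)] else lines
  items <- list()
  if (length(hdr)) {
    ends <- c(hdr[-1L] - 1L, length(lines))
    seen <- character()
    for (s in seq_along(hdr)) {
      block <- lines[hdr[s]:ends[s]]
      label <- sub("^\\s*\\[\\s*Item\\s*=\\s*([^]]*?)\\s*\\]\\s*$", "\\1",
                   block[1L])
      if (label %in% seen) {
        stop("duplicate item label '", label, "' at line ", hdr[s])
      }
      seen <- c(seen, label)
      kvl <- grep("=", block[-1L], value = TRUE)
      keys <- trimws(sub("=.*$", "", kvl))
      vals <- trimws(sub("^[^=]*=", "", kvl))
      items[[s]] <- list(label = label, lines = block,
                         kv = stats::setNames(vals, keys))
    }
  }
  structure(list(preamble = preamble, items = items),
            class = "navigator_document")
}

#' @export
print.navigator_document <- function(x, ...) {
  types <- vapply(x$items, function(it) nav_item_type(it), "")
  cat("navigator_document:", length(x$items), "items (",
      paste(sprintf("%d %s", table(types), names(table(types))),
            collapse = ", "), ")\n")
  invisible(x)
}

#' @rdname read_navigator
#' @param doc A `navigator_document`.
#' @export
write_navigator <- function(doc, path) {
  stopifnot(inherits(doc, "navigator_document"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  all_lines <- c(doc$preamble, unlist(lapply(doc$items, `[[`, "lines")))
  writeLines(all_lines, con, sep = "\n")
  invisible(path)
}

# numeric vector stored under a key of an item, NULL when absent
nav_num <- function(item, key) {
  if (!key %in% names(item$kv)) return(NULL)
  as.numeric(strsplit(trimws(item$kv[[key]]), "\\s+")[[1L]])
}

nav_item_type <- function(item) {
  t <- nav_num(item, "Type")
  if (is.null(t)) return("unknown")
  c("point", "polygon", "map")[t + 1L]
}

#' Find a navigator item by label
#'
#' @param doc A `navigator_document`.
#' @param label Item label.
#' @return The item (list), or an error if absent.
#' @export
nav_item <- function(doc, label) {
  for (it in doc$items) if (it$label == label) return(it)
  stop("no navigator item labelled '", label, "'")
}

#' Convert map pixel coordinates to stage coordinates
#'
#' For a Navigator map item carrying a scale matrix (key `MapScaleMat`,
#' four numbers, row-major, interpreted here as stage micrometers per
#' map pixel), a raw stage position (`RawStageXY`) and the map size
#' (`MapWidthHeight`), a pixel position `p` maps to
#' `stage = raw_stage + M (p - center)`, where `center` is the map
#' center in pixels. Because image rows grow downward while stage Y
#' conventionally grows upward, the pixel y offset is negated by default;
#' set `y_flip = FALSE` for installations with matching orientations.
#'
#' @param map_item A map item from [nav_item()].
#' @param points_px n x 2 matrix of (x, y) 0-based map pixel coordinates.
#' @param y_flip Negate the pixel y offset (default `TRUE`).
#' @return n x 2 matrix of stage coordinates (micrometers).
#' @export
pixel_to_stage <- function(map_item, points_px, y_flip = TRUE) {
  M <- nav_num(map_item, "MapScaleMat")
  if (is.null(M)) stop("map item '", map_item$label,
                       "' has no MapScaleMat")
  M <- matrix(M, 2L, 2L, byrow = TRUE)
  raw <- nav_num(map_item, "RawStageXY")
  wh <- nav_num(map_item, "MapWidthHeight")
  if (is.null(raw) || is.null(wh)) {
    stop("map item '", map_item$label,
         "' needs RawStageXY and MapWidthHeight")
  }
  pts <- matrix(as.numeric(as.matrix(points_px)), ncol = 2L)
  rel <- sweep(pts, 2L, (wh - 1) / 2)
  if (y_flip) rel[, 2L] <- -rel[, 2L]
  out <- rel %*% t(M)
  sweep(out, 2L, raw, `+`)
}

#' @rdname pixel_to_stage
#' @param points_stage n x 2 matrix of stage coordinates.
#' @export
stage_to_pixel <- function(map_item, points_stage, y_flip = TRUE) {
  M <- nav_num(map_item, "MapScaleMat")
  if (is.null(M)) stop("map item '", map_item$label,
                       "' has no MapScaleMat")
  M <- matrix(M, 2L, 2L, byrow = TRUE)
  raw <- nav_num(map_item, "RawStageXY")
  wh <- nav_num(map_item, "MapWidthHeight")
  pts <- matrix(as.numeric(as.matrix(points_stage)), ncol = 2L)
  rel <- sweep(pts, 2L, raw) %*% t(solve(M))
  if (y_flip) rel[, 2L] <- -rel[, 2L]
  sweep(rel, 2L, (wh - 1) / 2, `+`)
}

format_nav_num <- function(x) {
  paste(vapply(x, function(v) format(v, digits = 15, scientific = FALSE,
                                     trim = TRUE), ""), collapse = " ")
}

#' Append acquisition points for selected cells to a Navigator document
#'
#' Adds one point item per classified cell, labelled
#' `"<pattern>_<id>"`, with the acquire flag set and stage coordinates
#' computed from the cell's EM-overview centroid through
#' [pixel_to_stage()] on the named map item. Existing items are left
#' untouched, so the amended file drives automated high-resolution
#' acquisition of exactly the selected cells.
#'
#' @param doc A `navigator_document`.
#' @param map_label Label of the map item the pixel coordinates refer to.
#' @param cells Data frame from [detect_cells()].
#' @param calls Data frame from [classify_cells()]; only cells whose
#'   flags are `ok` or `low_confidence` in both tables are exported
#'   (manual reassignments count as classified).
#' @param y_flip Passed to [pixel_to_stage()].
#' @return The amended `navigator_document`.
#' @export
add_acquisition_points <- function(doc, map_label, cells, calls,
                                   y_flip = TRUE) {
  map <- nav_item(doc, map_label)
  if (nav_item_type(map) != "map") {
    stop("item '", map_label, "' is not a map item")
  }
  z <- nav_num(map, "StageXYZ")
  z <- if (is.null(z) || length(z) < 3L) 0 else z[3L]
  regis <- nav_num(map, "Regis")
  map_id <- nav_num(map, "MapID")

  sel <- merge(cells[cells$flags == "ok", c("id", "x", "y")],
               calls[calls$flags %in% c("ok", "low_confidence",
                                        "manual_override") &
                       !is.na(calls$pattern),
                     c("id", "pattern")], by = "id")
  existing <- vapply(doc$items, `[[`, "", "label")
  for (i in seq_len(nrow(sel))) {
    stage <- pixel_to_stage(map, cbind(sel$x[i], sel$y[i]), y_flip = y_flip)
    label <- sprintf("%s_%d", sel$pattern[i], sel$id[i])
    if (label %in% existing) {
      stop("point label '", label, "' already exists in the document")
    }
    existing <- c(existing, label)
    lines <- c("",
               sprintf("[Item = %s]", label),
               "Type = 0",
               "Color = 0",
               sprintf("StageXYZ = %s", format_nav_num(c(stage[1L, ], z))),
               "NumPts = 1",
               sprintf("PtsX = %s", format_nav_num(stage[1L, 1L])),
               sprintf("PtsY = %s", format_nav_num(stage[1L, 2L])),
               "Acquire = 1")
    if (!is.null(regis)) {
      lines <- c(lines, sprintf("Regis = %s", format_nav_num(regis)))
    }
    if (!is.null(map_id)) {
      lines <- c(lines, sprintf("DrawnID = %s", format_nav_num(map_id)))
    }
    kvl <- grep("=", lines[-(1:2)], value = TRUE)
    doc$items[[length(doc$items) + 1L]] <- list(
      label = label, lines = lines,
      kv = stats::setNames(trimws(sub("^[^=]*=", "", kvl)),
                           trimws(sub("=.*$", "", kvl))))
  }
  doc
}

#' Create a minimal Navigator document holding one registered map item
#'
#' Convenience for synthetic end-to-end runs: builds an
#' `AdocVersion = 2.00` document with a single map item describing the
#' EM overview frame.
#'
#' @param map_label Item label for the map.
#' @param width,height Map size in pixels.
#' @param stage_xy Stage position of the map center (micrometers).
#' @param scale Stage micrometers per pixel (isotropic).
#' @param map_id Numeric map id.
#' @return A `navigator_document`.
#' @export
nav_skeleton <- function(map_label = "overview", width = 1024,
                         height = 1024, stage_xy = c(0, 0),
                         scale = 0.01, map_id = 1) {
  lines <- c(sprintf("[Item = %s]", map_label),
             "Type = 2",
             "Color = 0",
             sprintf("StageXYZ = %s", format_nav_num(c(stage_xy, 0))),
             sprintf("RawStageXY = %s", format_nav_num(stage_xy)),
             sprintf("MapWidthHeight = %s", format_nav_num(c(width, height))),
             sprintf("MapScaleMat = %s",
                     format_nav_num(c(scale, 0, 0, scale))),
             sprintf("MapID = %s", format_nav_num(map_id)),
             "Regis = 1")
  kvl <- grep("=", lines[-1L], value = TRUE)
  structure(list(
    preamble = c("AdocVersion = 2.00", ""),
    items = list(list(label = map_label, lines = lines,
                      kv = stats::setNames(
                        trimws(sub("^[^=]*=", "", kvl)),
                        trimws(sub("=.*$", "", kvl)))))),
    class = "navigator_document")
}
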