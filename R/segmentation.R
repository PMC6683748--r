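#' Segmentation parameters for cell detection
#'
#' @param smoothing_radius_px Radius of the morphological opening/closing
#'   applied to the raw pixel classification before watershed, pixels.
#'   Default 3.
#' @param min_area_um2,max_area_um2 Area gate for accepted cell profiles,
#'   square micrometers. Defaults 3 and 80 (the range of yeast cross
#'   sections at medium magnification).
#' @param min_circularity Minimum circularity `4 * pi * A / P^2` of an
#'   accepted profile; 1 is a perfect circle. Default 0.6.
#' @param pixel_size_nm EM overview pixel size, nanometers per pixel.
#' @param marker_separation_um Minimum separation of watershed markers
#'   (local maxima of the distance transform), micrometers. Default 1.5.
#' @return A `segmentation_params` list.
#' @export
segmentation_params <- function(smoothing_radius_px = 3,
                                min_area_um2 = 3, max_area_um2 = 80,
                                min_circularity = 0.6,
                                pixel_size_nm = 12.5,
                                marker_separation_um = 1.5) {
  stopifnot(min_area_um2 < max_area_um2, min_circularity > 0,
            min_circularity <= 1, pixel_size_nm > 0,
            smoothing_radius_px >= 0, marker_separation_um > 0)
  structure(as.list(environment()), class = "segmentation_params")
}

CLASS_LEVELS <- c(background = 0L, cell = 1L, hole = 2L, debris = 3L)

check_class_map <- function(class_map) {
  if (length(dim(class_map)) == 3L) class_map <- prob_argmax(class_map)
  class_map <- matrix(as.integer(class_map), nrow(class_map),
                      ncol(class_map))
  bad <- setdiff(unique(as.vector(class_map)), CLASS_LEVELS)
  if (length(bad)) {
    stop("unknown class labels in map: ", paste(bad, collapse = ", "),
         " (expected 0=background, 1=cell, 2=hole, 3=debris)")
  }
  class_map
}

# morphological opening then closing with a disc brush; radius 0 = no-op.
# Works on a 0/1 matrix; symmetric kernel, so matrix orientation is moot.
smooth_binary <- function(mask, radius_px) {
  if (radius_px <= 0) return(mask)
  brush <- EBImage::makeBrush(2L * as.integer(radius_px) + 1L,
                              shape = "disc")
  m <- EBImage::closing(EBImage::opening(mask, brush), brush)
  matrix(as.numeric(m) > 0.5, nrow(mask), ncol(mask)) * 1
}

# 8-connected boundary trace of one labelled object; returns the contour
# as 0-based (x = col, y = row) vertices in order
trace_outline <- function(lab, id) {
  oc <- EBImage::ocontour(EBImage::Image(lab == id))[[1L]]
  # ocontour treats dim 1 as x; our dim 1 is row (= y)
  cbind(x = oc[, 2L] - 1, y = oc[, 1L] - 1)
}

polygon_perimeter <- function(xy) {
  nxt <- rbind(xy[-1L, , drop = FALSE], xy[1L, , drop = FALSE])
  sum(sqrt(rowSums((nxt - xy)^2)))
}

# watershed markers: local maxima (8-neighbourhood, plateaus included) of
# the distance transform, greedily suppressed so no two markers lie
# within sep_px of each other (highest first; raster order breaks ties)
find_markers <- function(d, sep_px) {
  nr <- nrow(d); nc <- ncol(d)
  pad <- matrix(-Inf, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- d
  nbr <- -Inf
  for (dr in -1:1) for (dc in -1:1) {
    if (dr || dc) {
      nbr <- pmax(nbr, pad[2:(nr + 1L) + dr, 2:(nc + 1L) + dc])
    }
  }
  cand <- which(d > 0 & d >= nbr, arr.ind = TRUE)
  if (!nrow(cand)) return(cand)
  h <- d[cand]
  ord <- order(-h, cand[, 1L], cand[, 2L])
  cand <- cand[ord, , drop = FALSE]
  h <- h[ord]
  # profile of the distance map along the straight line between two pixels
  line_min <- function(p, q) {
    n <- max(abs(p - q), 1L)
    rr <- round(seq(p[1L], q[1L], length.out = n + 1L))
    cc <- round(seq(p[2L], q[2L], length.out = n + 1L))
    min(d[cbind(rr, cc)])
  }
  tol <- 1
  keep <- integer()
  for (i in seq_len(nrow(cand))) {
    ok <- TRUE
    for (j in keep) {
      close_by <- (cand[j, 1L] - cand[i, 1L])^2 +
        (cand[j, 2L] - cand[i, 2L])^2 < sep_px^2
      # plateau/ridge maxima: no valley deeper than tol between the two
      # peaks means they seed the same object
      same_ridge <- line_min(cand[i, ], cand[j, ]) >= min(h[i], h[j]) - tol
      if (close_by || same_ridge) { ok <- FALSE; break }
    }
    if (ok) keep <- c(keep, i)
  }
  cand[keep, , drop = FALSE]
}

# split a binary blob into objects: markers from the distance transform,
# then seeded region growing (EBImage::propagate) up to the blob edge
split_blob <- function(crop, sep_px) {
  dist <- EBImage::distmap(crop)
  mk <- find_markers(as.matrix(dist), sep_px)
  if (nrow(mk) <= 1L) return((crop > 0) * 1L)
  seeds <- matrix(0L, nrow(crop), ncol(crop))
  seeds[mk] <- seq_len(nrow(mk))
  lab <- EBImage::propagate(dist, EBImage::Image(seeds), mask = crop > 0)
  matrix(as.integer(lab), nrow(crop), ncol(crop))
}

#' Detect cell profiles in an EM overview pixel-class map
#'
#' Extracts the cell class from a pixel classification of the EM overview,
#' smooths it morphologically, separates touching cells by marker-based
#' watershed on the Euclidean distance transform, and filters the
#' resulting objects by area and circularity. All detected objects are
#' returned; gating only sets flags, so rejected objects remain available
#' for inspection.
#'
#' @param class_map Integer label matrix (0 = background, 1 = cell,
#'   2 = hole, 3 = debris) or a row x col x class probability array
#'   (argmax-converted, class order = labels 0..k-1).
#' @param params A [segmentation_params()].
#' @return A data frame of cell records: `id`, `x`, `y` (centroid, 0-based
#'   EM pixels), `area_px`, `area_um2`, `circularity`, `flags` (comma
#'   string over ok / excluded_size / excluded_shape / edge_touching),
#'   with the outlines as a list-column `outline` of n x 2 matrices. Ids
#'   are assigned in raster order (y, then x) of the centroids.
#' @export
detect_cells <- function(class_map, params = segmentation_params()) {
  class_map <- check_class_map(class_map)
  mask <- smooth_binary((class_map == CLASS_LEVELS[["cell"]]) * 1,
                        params$smoothing_radius_px)
  empty <- data.frame(id = integer(), x = numeric(), y = numeric(),
                      area_px = numeric(), area_um2 = numeric(),
                      circularity = numeric(), flags = character())
  empty$outline <- list()
  if (!any(mask > 0)) return(empty)

  px_um <- params$pixel_size_nm / 1000
  sep_px <- max(1, round(params$marker_separation_um / px_um))

  # label connected blobs first, then split each by marker-based watershed
  # on its own distance transform inside a cropped bounding box; cost then
  # scales with the blobs, not with the overview size
  comp <- matrix(as.integer(EBImage::bwlabel(mask)), nrow(mask), ncol(mask))
  n_comp <- max(comp)
  if (n_comp == 0L) return(empty)

  recs <- list()
  for (b in seq_len(n_comp)) {
    pix_b <- which(comp == b, arr.ind = TRUE)
    r0 <- max(1L, min(pix_b[, 1L]) - 1L)
    r1 <- min(nrow(mask), max(pix_b[, 1L]) + 1L)
    c0 <- max(1L, min(pix_b[, 2L]) - 1L)
    c1 <- min(ncol(mask), max(pix_b[, 2L]) + 1L)
    crop <- (comp[r0:r1, c0:c1, drop = FALSE] == b) * 1
    lab <- split_blob(crop, sep_px)
    for (i in seq_len(max(lab))) {
      pix <- which(lab == i, arr.ind = TRUE)
      area_px <- nrow(pix)
      cx <- mean(pix[, 2L]) + c0 - 2       # 0-based global x
      cy <- mean(pix[, 1L]) + r0 - 2
      outline <- trace_outline(lab, i)
      outline[, 1L] <- outline[, 1L] + c0 - 1L
      outline[, 2L] <- outline[, 2L] + r0 - 1L
      per <- polygon_perimeter(outline)
      circ <- if (per > 0) min(4 * pi * area_px / per^2, 1) else 0
      area_um2 <- area_px * px_um^2
      edge <- any((pix[, 1L] + r0 - 1L) %in% c(1L, nrow(mask))) ||
        any((pix[, 2L] + c0 - 1L) %in% c(1L, ncol(mask)))
      flags <- character()
      if (area_um2 < params$min_area_um2 ||
          area_um2 > params$max_area_um2) {
        flags <- c(flags, "excluded_size")
      }
      if (circ < params$min_circularity) flags <- c(flags, "excluded_shape")
      if (edge) flags <- c(flags, "edge_touching")
      if (!length(flags)) flags <- "ok"
      recs[[length(recs) + 1L]] <-
        list(x = cx, y = cy, area_px = area_px, area_um2 = area_um2,
             circularity = circ, flags = paste(flags, collapse = ","),
             outline = outline)
    }
  }

  df <- data.frame(
    x = vapply(recs, `[[`, 0, "x"),
    y = vapply(recs, `[[`, 0, "y"),
    area_px = vapply(recs, `[[`, 0, "area_px"),
    area_um2 = vapply(recs, `[[`, 0, "area_um2"),
    circularity = vapply(recs, `[[`, 0, "circularity"),
    flags = vapply(recs, `[[`, "", "flags")
  )
  # canonical ids: raster order of centroids, independent of how the
  # labelling enumerated objects
  ord <- order(round(df$y), round(df$x))
  df <- df[ord, , drop = FALSE]
  df <- cbind(id = seq_len(nrow(df)), df)
  rownames(df) <- NULL
  df$outline <- lapply(recs, `[[`, "outline")[ord]
  df
}

#' Binary mask of hole and debris pixels
#'
#' Union of the hole and debris classes of the pixel-class map, smoothed
#' with the same morphological opening/closing as the cell class. Used to
#' subtract damaged regions from measurement masks.
#'
#' @inheritParams detect_cells
#' @return Logical matrix, `TRUE` on hole/debris pixels.
#' @export
holes_mask <- function(class_map, params = segmentation_params()) {
  class_map <- check_class_map(class_map)
  raw <- class_map == CLASS_LEVELS[["hole"]] |
    class_map == CLASS_LEVELS[["debris"]]
  smooth_binary(raw * 1, params$smoothing_radius_px) > 0
}

#' Write / read detected cells as CSV
#'
#' `write_cells` writes two CSVs: the per-cell table (id, x, y, area_px,
#' area_um2, circularity, flags) and the outlines as a long polygon table
#' (id, vertex, x, y).
#'
#' @param cells Data frame from [detect_cells()].
#' @param path Base path; `"<path>.csv"` and `"<path>_outlines.csv"` are
#'   written.
#' @export
write_cells <- function(cells, path) {
  flat <- cells[setdiff(names(cells), "outline")]
  utils::write.csv(flat, paste0(path, ".csv"), row.names = FALSE,
                   quote = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    o <- cells$outline[[i]]
    data.frame(id = cells$id[i], vertex = seq_len(nrow(o)),
               x = o[, 1L], y = o[, 2L])
  }))
  if (is.null(out)) out <- data.frame(id = integer(), vertex = integer(),
                                      x = numeric(), y = numeric())
  utils::write.csv(out, paste0(path, "_outlines.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_cells
#' @export
read_cells <- function(path) {
  flat <- utils::read.csv(paste0(path, ".csv"))
  out <- utils::read.csv(paste0(path, "_outlines.csv"))
  flat$outline <- lapply(flat$id, function(i) {
    o <- out[out$id == i, c("x", "y")]
    cbind(x = o$x, y = o$y)
  })
  flat
}
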