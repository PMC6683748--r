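#' Build per-cell measurement masks in the LM frame
#'
#' Transforms each accepted cell outline from the EM overview into the LM
#' frame and converts it to a measurement mask by morphological dilation.
#' The default `"band"` style dilates the outline curve itself, yielding
#' an annular band that tracks the cell wall — where the stain ring lies,
#' on and just outside the EM-derived outline — without flooding the
#' unstained interior whose pixels would otherwise dominate the median.
#' (`style = "filled"` fills the outline before dilating instead.)
#' Pixels claimed by more than one cell, and pixels falling on holes or
#' debris, are removed from every claimant, so masks are pairwise
#' disjoint and measurements unbiased by neighbours or damaged regions.
#'
#' @param cells Data frame from [detect_cells()] (EM-frame outlines).
#'   Only rows whose flags are exactly `"ok"` receive masks.
#' @param holes Logical EM-frame matrix from [holes_mask()], or `NULL`.
#' @param transform [affine2d()] mapping EM pixels to LM pixels.
#' @param lm_dim Dimensions (rows, cols) of the LM image.
#' @param dilation_um Dilation margin, micrometers. Default 0.2.
#' @param lm_pixel_size_um LM pixel size, micrometers. Default 0.1.
#' @param style `"band"` (default) or `"filled"`.
#' @return A `measurement_masks` object: list with `dim`, and `masks` — a
#'   list per cell of `id`, `idx` (linear indices into an LM-frame
#'   matrix), and `flag` (`"ok"` or `"excluded_outside"`).
#' @export
build_masks <- function(cells, holes, transform, lm_dim,
                        dilation_um = 0.2, lm_pixel_size_um = 0.1,
                        style = c("band", "filled")) {
  style <- match.arg(style)
  stopifnot(inherits(transform, "affine2d"), dilation_um >= 0,
            lm_pixel_size_um > 0, length(lm_dim) == 2L)
  if (transform$direction != "em_to_lm") {
    stop("build_masks needs an EM-to-LM transform; got direction ",
         transform$direction)
  }
  nr <- lm_dim[1L]; nc <- lm_dim[2L]
  dil_px <- round(dilation_um / lm_pixel_size_um)
  brush <- if (dil_px > 0) {
    EBImage::makeBrush(2L * dil_px + 1L, shape = "disc")
  } else NULL

  ok <- cells[cells$flags == "ok", , drop = FALSE]
  masks <- vector("list", nrow(ok))
  claim <- matrix(0L, nr, nc)

  for (m in seq_len(nrow(ok))) {
    pts <- affine_apply(transform, ok$outline[[m]])
    col1 <- round(pts[, 1L]) + 1L   # 1-based matrix coords
    row1 <- round(pts[, 2L]) + 1L
    inside <- row1 >= 1L & row1 <= nr & col1 >= 1L & col1 <= nc
    if (!any(inside)) {
      masks[[m]] <- list(id = ok$id[m], idx = integer(),
                         flag = "excluded_outside")
      next
    }
    # fill the transformed outline inside its padded bounding box
    pad <- dil_px + 2L
    r0 <- max(1L, min(row1[inside]) - pad); r1 <- min(nr, max(row1[inside]) + pad)
    c0 <- max(1L, min(col1[inside]) - pad); c1 <- min(nc, max(col1[inside]) + pad)
    crop <- matrix(0, r1 - r0 + 1L, c1 - c0 + 1L)
    keep <- inside
    crop[cbind(row1[keep] - r0 + 1L, col1[keep] - c0 + 1L)] <- 1
    if (style == "filled") {
      m_crop <- EBImage::fillHull(crop)
      if (!is.null(brush)) m_crop <- EBImage::dilate(m_crop, brush)
    } else {
      # band: the outline curve dilated, clipped one pixel into the
      # interior so the band hugs the wall instead of the lumen
      m_crop <- if (!is.null(brush)) EBImage::dilate(crop, brush) else crop
      inner <- EBImage::erode(EBImage::fillHull(crop),
                              EBImage::makeBrush(3L, shape = "disc"))
      m_crop <- as.matrix(m_crop) * (1 - as.matrix(inner))
    }
    pix <- which(as.matrix(m_crop) > 0.5, arr.ind = TRUE)
    rows <- pix[, 1L] + r0 - 1L
    cols <- pix[, 2L] + c0 - 1L
    idx <- (cols - 1L) * nr + rows
    masks[[m]] <- list(id = ok$id[m], idx = idx, flag = "ok")
    claim[idx] <- claim[idx] + 1L
  }

  # symmetric overlap subtraction: contested pixels leave every mask
  contested <- which(claim > 1L)
  # holes/debris are EM-frame; warp into the LM frame by inverse lookup
  if (!is.null(holes) && any(holes)) {
    inv <- affine_invert(transform)     # LM -> EM
    lm_xy <- cbind(rep(0:(nc - 1L), each = nr), rep.int(0:(nr - 1L), nc))
    em_xy <- affine_apply(inv, lm_xy)
    er <- round(em_xy[, 2L]) + 1L
    ec <- round(em_xy[, 1L]) + 1L
    inb <- er >= 1L & er <= nrow(holes) & ec >= 1L & ec <= ncol(holes)
    hole_lm <- logical(nr * nc)
    hole_lm[inb] <- holes[cbind(er[inb], ec[inb])]
    contested <- union(contested, which(hole_lm))
  }
  if (length(contested)) {
    drop <- logical(nr * nc)
    drop[contested] <- TRUE
    for (m in seq_along(masks)) {
      masks[[m]]$idx <- masks[[m]]$idx[!drop[masks[[m]]$idx]]
    }
  }
  structure(list(dim = c(nr, nc), masks = masks),
            class = "measurement_masks")
}

#' @export
print.measurement_masks <- function(x, ...) {
  n_ok <- sum(vapply(x$masks, function(m) m$flag == "ok", TRUE))
  cat("measurement_masks:", length(x$masks), "cells (", n_ok, "ok ) in a",
      paste(x$dim, collapse = "x"), "LM frame\n")
  invisible(x)
}

#' Measure per-cell median intensities in each fluorescent channel
#'
#' Applies the LM-frame measurement masks to the multi-channel LM stack
#' and reports, for every cell, the median pixel intensity per channel
#' and the mask pixel count. Cells with an empty mask are emitted with
#' missing values and flagged.
#'
#' @param lm_stack row x col x channel numeric array (or a matrix for a
#'   single channel).
#' @param masks A `measurement_masks` object from [build_masks()].
#' @param channels Channel names; defaults to `dimnames` or `ch1..chN`.
#' @return Data frame: `id`, `n_px`, `flag`, one column per channel.
#' @export
measure_intensities <- function(lm_stack, masks, channels = NULL) {
  if (length(dim(lm_stack)) == 2L) {
    lm_stack <- array(lm_stack, c(dim(lm_stack), 1L))
  }
  stopifnot(inherits(masks, "measurement_masks"),
            all(dim(lm_stack)[1:2] == masks$dim))
  n_ch <- dim(lm_stack)[3L]
  if (is.null(channels)) {
    channels <- dimnames(lm_stack)[[3L]]
    if (is.null(channels)) channels <- paste0("ch", seq_len(n_ch))
  }
  plane_len <- prod(masks$dim)
  rows <- lapply(masks$masks, function(m) {
    vals <- if (length(m$idx)) {
      vapply(seq_len(n_ch), function(ch) {
        stats::median(lm_stack[m$idx + (ch - 1L) * plane_len])
      }, 0)
    } else rep(NA_real_, n_ch)
    flag <- if (!length(m$idx)) {
      if (m$flag == "ok") "empty_mask" else m$flag
    } else m$flag
    c(list(id = m$id, n_px = length(m$idx), flag = flag),
      as.list(vals))
  })
  df <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r, col.names = c("id", "n_px", "flag", channels),
                  check.names = FALSE)
  }))
  if (is.null(df)) {
    df <- as.data.frame(c(list(id = integer(), n_px = integer(),
                               flag = character()),
                          stats::setNames(rep(list(numeric()), n_ch),
                                          channels)),
                        check.names = FALSE)
  }
  rownames(df) <- NULL
  df
}

#' Write / read an intensity table CSV
#'
#' Columns: `id`, `n_px`, `flag`, then one column per channel in panel
#' order.
#'
#' @param table Data frame from [measure_intensities()].
#' @param path CSV path.
#' @export
write_intensities <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_intensities
#' @export
read_intensities <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}
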