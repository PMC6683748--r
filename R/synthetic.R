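#' Noise model for synthetic barcoded samples
#'
#' The generator emulates ring-stained (cell-wall) fluorescence of pooled
#' barcoded cells. Three stochastic components are modelled:
#' \describe{
#'   \item{brightness}{a per-cell log-normal factor shared across channels,
#'     reproducing the variable total amount of labelling with highly
#'     correlated intensity between channels;}
#'   \item{channel CV}{a per-cell, per-channel multiplicative Gaussian
#'     spread of the ring intensity (staining heterogeneity between
#'     conjugates on the same cell);}
#'   \item{pixel noise}{additive Gaussian camera/readout noise per pixel.}
#' }
#'
#' @param brightness_mean Mean ring intensity of a stained channel (camera
#'   units). Default 100.
#' @param brightness_sdlog Log-normal sigma of the shared per-cell
#'   brightness factor. Default 0.3.
#' @param channel_cv Coefficient of variation of the per-cell per-channel
#'   ring intensity. Default 0.10.
#' @param background Constant background level added everywhere. Default 20.
#' @param pixel_sd Additive Gaussian noise per pixel, as a fraction of the
#'   local ring intensity (0.10 means sd = 10\% of the ring signal);
#'   applied to background pixels at the background level. Default 0.10.
#' @return A `noise_config` list.
#' @export
noise_config <- function(brightness_mean = 100, brightness_sdlog = 0.3,
                         channel_cv = 0.10, background = 20,
                         pixel_sd = 0.10) {
  stopifnot(brightness_mean > 0, brightness_sdlog >= 0, channel_cv >= 0,
            background >= 0, pixel_sd >= 0)
  structure(list(brightness_mean = brightness_mean,
                 brightness_sdlog = brightness_sdlog,
                 channel_cv = channel_cv,
                 background = background,
                 pixel_sd = pixel_sd), class = "noise_config")
}

# Draw per-cell ground truth: pattern assignment, brightness factor and
# per-channel ring intensities under a noise config. Internal.
draw_cell_intensities <- function(patterns, n_per_pattern, noise) {
  n_cells <- length(patterns) * n_per_pattern
  pat_idx <- sample(rep(seq_along(patterns), each = n_per_pattern))
  brightness <- stats::rlnorm(n_cells,
                              meanlog = log(noise$brightness_mean),
                              sdlog = noise$brightness_sdlog)
  n_ch <- length(patterns[[1L]])
  ring <- matrix(0, n_cells, n_ch)
  for (i in seq_len(n_cells)) {
    bits <- patterns[[pat_idx[i]]]
    eps <- stats::rnorm(n_ch, 0, noise$channel_cv)
    ring[i, ] <- brightness[i] * bits * pmax(1 + eps, 0)
  }
  list(pattern_index = pat_idx, brightness = brightness, ring = ring)
}

#' Simulate a measured intensity table without rendering images
#'
#' Samples per-cell per-channel median ring intensities directly from the
#' generator's intensity model (see [noise_config()]): the value a
#' noiseless measurement stage would report is `brightness x bit x
#' (1 + channel CV) + background`, plus the sampling noise of a median over
#' `n_px` noisy ring pixels. This is the fast path for benchmarking the
#' barcode classifier at population sizes where rendering full image pairs
#' is unnecessary.
#'
#' @param panel A [channel_panel()].
#' @param patterns Patterns in use (list of bit vectors or strings);
#'   default all `2^n - 1`.
#' @param n_per_pattern Cells per pattern.
#' @param noise A [noise_config()].
#' @param n_px Nominal ring pixel count per cell (controls median noise).
#' @param seed Integer seed; identical arguments reproduce the table
#'   bit-for-bit.
#' @return List with `intensities` (data frame: id, n_px, one column per
#'   channel) and `truth` (data frame: id, pattern, brightness).
#' @export
simulate_intensities <- function(panel, patterns = NULL, n_per_pattern = 100,
                                 noise = noise_config(), n_px = 250,
                                 seed = 1) {
  panel <- as_panel(panel)
  if (is.null(patterns)) patterns <- enumerate_patterns(panel)
  patterns <- check_patterns(patterns, panel)
  withr::with_seed(seed, {
    d <- draw_cell_intensities(patterns, n_per_pattern, noise)
    n_cells <- length(d$pattern_index)
    # sd of the median of n iid normals ~ 1.2533 sd / sqrt(n)
    med_sd <- 1.2533 * noise$pixel_sd *
      pmax(d$ring, noise$background) / sqrt(n_px)
    vals <- d$ring + noise$background +
      matrix(stats::rnorm(length(d$ring)), n_cells) * med_sd
    vals <- pmax(vals, 0)
  })
  colnames(vals) <- panel$names
  labels <- vapply(patterns, attr, "", which = "label")
  list(
    intensities = data.frame(id = seq_len(n_cells), n_px = n_px, vals,
                             check.names = FALSE),
    truth = data.frame(id = seq_len(n_cells),
                       pattern = labels[d$pattern_index],
                       brightness = d$brightness)
  )
}

#' Geometry of a rendered synthetic sample
#'
#' @param lm_size LM image side length, pixels. Default 800, sized so
#'   the default four-channel panel at 8 cells per pattern (120 cells)
#'   places without overlap.
#' @param lm_pixel_size_um LM pixel size, micrometers. Default 0.1.
#' @param cell_diameter_um Mean cell diameter. Default 4 (yeast).
#' @param cell_diameter_cv CV of the cell diameter. Default 0.08.
#' @param ring_px Ring (cell wall) thickness, LM pixels. Default 2.
#' @param min_gap_px Minimum empty gap between cell rims. Default 4.
#' @param em_scale,em_rotation_deg LM-to-EM similarity: scale (default 8,
#'   medium-magnification EM pixels per LM pixel) and rotation (default 7
#'   degrees).
#' @param n_holes,n_debris Numbers of hole / debris distractor blobs in the
#'   EM frame. Defaults 5 and 5.
#' @param max_place_tries Rejection-sampling budget per cell before the
#'   generator refuses the requested density. Default 2000.
#' @return A `sample_geometry` list.
#' @export
sample_geometry <- function(lm_size = 800, lm_pixel_size_um = 0.1,
                            cell_diameter_um = 4, cell_diameter_cv = 0.08,
                            ring_px = 2, min_gap_px = 4,
                            em_scale = 8, em_rotation_deg = 7,
                            n_holes = 5, n_debris = 5,
                            max_place_tries = 2000) {
  stopifnot(lm_size >= 32, lm_pixel_size_um > 0, cell_diameter_um > 0,
            em_scale > 0)
  structure(as.list(environment()), class = "sample_geometry")
}

# Fill `expr` over a disk/annulus: applies f(values, d) on the pixels of
# `img` within radius [r_in, r_out] of center (x, y) (0-based). Internal.
annulus_pixels <- function(dim_rc, cx, cy, r_in, r_out) {
  rows <- max(1L, floor(cy - r_out) + 1L):min(dim_rc[1L], ceiling(cy + r_out) + 1L)
  cols <- max(1L, floor(cx - r_out) + 1L):min(dim_rc[2L], ceiling(cx + r_out) + 1L)
  d <- sqrt(outer((rows - 1 - cy)^2, (cols - 1 - cx)^2, `+`))
  sel <- d >= r_in & d <= r_out
  cbind(row = rep.int(rows, length(cols))[as.vector(sel)],
        col = rep(cols, each = length(rows))[as.vector(sel)])
}

#' Render a ground-truthed synthetic LM/EM sample pair
#'
#' Generates the full input set of a multiplexed CLEM experiment with known
#' ground truth: a multi-channel LM image of ring-stained cells (one plane
#' per fluorescent channel), the matching EM overview and pixel-class map
#' in an EM frame related to the LM frame by a known similarity transform,
#' hole and debris distractors, a complete truth table, and noiseless
#' landmark pairs for registration.
#'
#' Cells are ellipses (circles by default) whose wall ring carries, in each
#' channel, `brightness x bit + background` plus noise (see
#' [noise_config()]). The class map labels pixels 0 = background (resin),
#' 1 = cell, 2 = hole, 3 = debris.
#'
#' @inheritParams simulate_intensities
#' @param geometry A [sample_geometry()].
#' @param n_control_points Number of exact LM/EM landmark pairs to emit.
#' @return A `synthetic_sample` list: `lm_stack` (row x col x channel
#'   array), `em_overview` (matrix), `class_map` (integer matrix),
#'   `truth` (data frame: id, pattern, brightness, lm/em centroids,
#'   radius), `lm_to_em` ([affine2d()]), `control_points`, `panel`,
#'   `noise`, `geometry`, `seed`.
#' @export
render_sample <- function(panel, patterns = NULL, n_per_pattern = 8,
                          noise = noise_config(),
                          geometry = sample_geometry(),
                          n_control_points = 6, seed = 1) {
  panel <- as_panel(panel)
  if (is.null(patterns)) patterns <- enumerate_patterns(panel)
  patterns <- check_patterns(patterns, panel)
  g <- geometry
  labels <- vapply(patterns, attr, "", which = "label")

  withr::with_seed(seed, {
    d <- draw_cell_intensities(patterns, n_per_pattern, noise)
    n_cells <- length(d$pattern_index)
    radius <- stats::rnorm(n_cells,
                           mean = g$cell_diameter_um / 2 / g$lm_pixel_size_um,
                           sd = g$cell_diameter_cv * g$cell_diameter_um / 2 /
                             g$lm_pixel_size_um)
    radius <- pmax(radius, 3)

    # rejection-sample non-overlapping centers in the LM frame
    cx <- numeric(n_cells); cy <- numeric(n_cells)
    margin <- radius + g$ring_px + 2
    for (i in seq_len(n_cells)) {
      placed <- FALSE
      for (try in seq_len(g$max_place_tries)) {
        px <- stats::runif(1, margin[i], g$lm_size - 1 - margin[i])
        py <- stats::runif(1, margin[i], g$lm_size - 1 - margin[i])
        if (i == 1L || all(sqrt((cx[seq_len(i - 1L)] - px)^2 +
                                (cy[seq_len(i - 1L)] - py)^2) >=
                           radius[seq_len(i - 1L)] + radius[i] +
                           2 * g$ring_px + g$min_gap_px)) {
          cx[i] <- px; cy[i] <- py; placed <- TRUE; break
        }
      }
      if (!placed) {
        stop("could not place ", n_cells, " cells of radius ~",
             round(mean(radius)), " px in a ", g$lm_size,
             " px frame without overlap; reduce density")
      }
    }

    # LM stack: ring signal + background + pixel noise
    n_ch <- panel$count
    lm <- array(noise$background, c(g$lm_size, g$lm_size, n_ch))
    # the stain ring sits on/just outside the wall, i.e. outside the
    # EM-derived outline at radius r: annulus [r, r + ring_px]
    for (i in seq_len(n_cells)) {
      px <- annulus_pixels(c(g$lm_size, g$lm_size), cx[i], cy[i],
                           radius[i], radius[i] + g$ring_px)
      for (ch in seq_len(n_ch)) {
        idx <- cbind(px, ch)
        lm[idx] <- d$ring[i, ch] + noise$background
      }
    }
    if (noise$pixel_sd > 0) {
      lm <- lm + array(stats::rnorm(length(lm)), dim(lm)) *
        (noise$pixel_sd * lm)
      lm <- pmax(lm, 0)
    }

    # EM frame: similarity transform of the LM frame, auto-translated so
    # the mapped LM square sits inside the EM image with a small margin
    tf0 <- affine_similarity(g$em_scale, g$em_rotation_deg, c(0, 0),
                             direction = "lm_to_em")
    corners <- cbind(c(0, g$lm_size - 1, 0, g$lm_size - 1),
                     c(0, 0, g$lm_size - 1, g$lm_size - 1))
    mapped <- affine_apply(tf0, corners)
    em_margin <- 8
    translation <- em_margin - apply(mapped, 2L, min)
    lm_to_em <- affine_similarity(g$em_scale, g$em_rotation_deg,
                                  translation, direction = "lm_to_em")
    mapped <- affine_apply(lm_to_em, corners)
    em_size <- ceiling(max(mapped)) + em_margin + 1

    em_centers <- affine_apply(lm_to_em, cbind(cx, cy))
    em_radius <- radius * g$em_scale

    class_map <- matrix(0L, em_size, em_size)
    em <- matrix(0.55, em_size, em_size)          # resin gray
    for (i in seq_len(n_cells)) {
      body <- annulus_pixels(dim(class_map), em_centers[i, 1L],
                             em_centers[i, 2L], 0, em_radius[i])
      class_map[body] <- 1L
      em[body] <- 0.45
      wall <- annulus_pixels(dim(em), em_centers[i, 1L], em_centers[i, 2L],
                             em_radius[i] - g$em_scale,
                             em_radius[i])
      em[wall] <- 0.2                              # dark cell wall
    }

    # distractors: holes (bright, resin torn out) and debris (dark blobs),
    # placed clear of cells
    place_blob <- function(r_blob) {
      for (try in seq_len(g$max_place_tries)) {
        bx <- stats::runif(1, r_blob + 2, em_size - r_blob - 3)
        by <- stats::runif(1, r_blob + 2, em_size - r_blob - 3)
        if (all(sqrt((em_centers[, 1L] - bx)^2 + (em_centers[, 2L] - by)^2) >
                em_radius + r_blob + g$min_gap_px * g$em_scale)) {
          return(c(bx, by))
        }
      }
      NULL
    }
    hole_radius <- g$cell_diameter_um / 2 / g$lm_pixel_size_um * g$em_scale
    for (b in seq_len(g$n_holes)) {
      r_blob <- stats::runif(1, 0.6, 1.2) * hole_radius
      pos <- place_blob(r_blob)
      if (is.null(pos)) next
      px <- annulus_pixels(dim(class_map), pos[1L], pos[2L], 0, r_blob)
      class_map[px] <- 2L
      em[px] <- 0.95
    }
    for (b in seq_len(g$n_debris)) {
      r_blob <- stats::runif(1, 0.15, 0.45) * hole_radius
      pos <- place_blob(r_blob)
      if (is.null(pos)) next
      px <- annulus_pixels(dim(class_map), pos[1L], pos[2L], 0, r_blob)
      class_map[px] <- 3L
      em[px] <- 0.08
    }
    if (noise$pixel_sd > 0) {
      em <- em + matrix(stats::rnorm(length(em), 0, 0.02), nrow(em))
      em <- pmin(pmax(em, 0), 1)
    }

    # exact landmark pairs on a coarse grid across the LM frame
    gp <- seq(0.12, 0.88, length.out = ceiling(sqrt(n_control_points)))
    grid <- as.matrix(expand.grid(x = gp, y = gp)) * (g$lm_size - 1)
    grid <- grid[seq_len(min(n_control_points, nrow(grid))), , drop = FALSE]
    cp_em <- affine_apply(lm_to_em, grid)
    control_points <- data.frame(em_x = cp_em[, 1L], em_y = cp_em[, 2L],
                                 lm_x = grid[, 1L], lm_y = grid[, 2L])
  })

  truth <- data.frame(id = seq_len(n_cells),
                      pattern = labels[d$pattern_index],
                      brightness = d$brightness,
                      lm_x = cx, lm_y = cy,
                      em_x = em_centers[, 1L], em_y = em_centers[, 2L],
                      radius_lm_px = radius)
  ring <- d$ring + noise$background
  colnames(ring) <- panel$names

  structure(list(lm_stack = lm, em_overview = em, class_map = class_map,
                 truth = truth, ring_intensity = ring,
                 lm_to_em = lm_to_em, control_points = control_points,
                 panel = panel, patterns = patterns, noise = noise,
                 geometry = g, seed = seed),
            class = "synthetic_sample")
}

#' @export
print.synthetic_sample <- function(x, ...) {
  cat("synthetic_sample:", nrow(x$truth), "cells,",
      x$panel$count, "channels, LM", paste(dim(x$lm_stack)[1:2],
                                           collapse = "x"),
      "px, EM", paste(dim(x$em_overview), collapse = "x"), "px, seed",
      x$seed, "\n")
  invisible(x)
}

#' Write a synthetic sample to disk
#'
#' Writes `lm.tif` (multi-page 32-bit float TIFF, one page per channel),
#' `em.tif` (float TIFF), `class_map.tif` (8-bit integer TIFF),
#' `truth.csv`, `control_points.csv` and `lm_to_em.txt`.
#'
#' @param sample A `synthetic_sample` from [render_sample()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sample <- function(sample, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  # camera units are stored scaled by 2^16 so the float TIFF stays in the
  # [0, 1] range the tiff package guarantees; read_lm_stack undoes this
  pages <- lapply(seq_len(dim(sample$lm_stack)[3L]),
                  function(ch) sample$lm_stack[, , ch] / LM_TIFF_SCALE)
  tiff::writeTIFF(pages, file.path(dir, "lm.tif"), bits.per.sample = 32L,
                  reduce = FALSE)
  tiff::writeTIFF(sample$em_overview, file.path(dir, "em.tif"),
                  bits.per.sample = 32L, reduce = FALSE)
  tiff::writeTIFF(sample$class_map / 255, file.path(dir, "class_map.tif"),
                  bits.per.sample = 8L)
  utils::write.csv(sample$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE, quote = FALSE)
  write_control_points(sample$control_points,
                       file.path(dir, "control_points.csv"))
  write_affine(sample$lm_to_em, file.path(dir, "lm_to_em.txt"))
  writeLines(sample$panel$names, file.path(dir, "channels.txt"))
  invisible(dir)
}

#' Read a ground-truth table written by [write_sample()]
#'
#' The `pattern` column is kept as character so barcode strings with
#' leading zeros survive.
#'
#' @param path `truth.csv` path.
#' @return Data frame of per-cell ground truth.
#' @export
read_truth <- function(path) {
  utils::read.csv(path, colClasses = c(pattern = "character"))
}

#' Read a class-map raster
#'
#' Accepts an integer label TIFF (class codes 0-3) or a multi-page
#' per-class probability TIFF, which is argmax-converted to labels
#' (page 1 = class 0).
#'
#' @param path TIFF file.
#' @return Integer matrix of class labels.
#' @export
read_class_map <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) == 1L) {
    m <- pages[[1L]]
    if (length(dim(m)) == 3L) m <- m[, , 1L]
    return(matrix(as.integer(round(m * 255)), nrow(m), ncol(m)))
  }
  prob_argmax(simplify2array(pages)) # pages = classes 0..k-1
}

# argmax over the 3rd dimension of a per-class probability array,
# returning labels 0..k-1
prob_argmax <- function(arr) {
  stopifnot(length(dim(arr)) == 3L)
  lab <- apply(arr, c(1L, 2L), which.max) - 1L
  matrix(as.integer(lab), dim(arr)[1L], dim(arr)[2L])
}

LM_TIFF_SCALE <- 65536

#' Read a multi-channel LM stack from a multi-page TIFF
#'
#' Inverse of the `lm.tif` written by [write_sample()]: intensities are
#' rescaled back to camera units.
#'
#' @param path TIFF file, one 2D page per fluorescent channel.
#' @return row x col x channel numeric array.
#' @export
read_lm_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  pages <- lapply(pages, function(m) if (length(dim(m)) == 3L) m[, , 1L] else m)
  simplify2array(pages) * LM_TIFF_SCALE
}

#' Configuration for the sphere-slicing stereology simulator
#'
#' Cells are spheres containing smaller non-overlapping organelle spheres;
#' each cell can be cut by one random plane, emulating profile-based
#' sampling of thin sections. A cell of radius R is hit by the section
#' with probability proportional to R (larger cells present more section
#' positions), and the plane offset within a hit cell is uniform over
#' (-R, R); this makes the areal (Delesse) ratio a consistent estimator of
#' the population volume fraction.
#'
#' @param n_cells Number of cells in the population. Default 1000.
#' @param cell_radius_mean Mean cell radius (micrometers). Default 2.
#' @param cell_radius_cv CV of cell radius (log-normal). Default 0.1.
#' @param organelle_count_mean Mean organelles per cell (Poisson).
#'   Default 1.5.
#' @param organelle_radius_mean Mean organelle radius. Default 0.25.
#' @param organelle_radius_cv CV of organelle radius (log-normal).
#'   Default 0.2.
#' @param seed Integer seed.
#' @return A `sphere_slice_config` list.
#' @export
sphere_slice_config <- function(n_cells = 1000, cell_radius_mean = 2,
                                cell_radius_cv = 0.1,
                                organelle_count_mean = 1.5,
                                organelle_radius_mean = 0.25,
                                organelle_radius_cv = 0.2, seed = 1) {
  stopifnot(n_cells >= 1, cell_radius_mean > 0, cell_radius_cv >= 0,
            organelle_count_mean >= 0, organelle_radius_mean > 0,
            organelle_radius_mean < cell_radius_mean)
  structure(as.list(environment()), class = "sphere_slice_config")
}

# log-normal with given mean and CV
rlnorm_mean_cv <- function(n, mean, cv) {
  if (cv <= 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Slice a population of organelle-bearing spherical cells
#'
#' Generates a 3D population per [sphere_slice_config()], sections it with
#' random planes, and returns the per-profile measurements that feed the
#' stereological estimators, together with the exact population volume
#' fraction (sum of organelle volumes over sum of cell volumes) and the
#' exact organelle surface-to-volume ratio.
#'
#' Organelle spheres are placed uniformly inside their cell, rejected
#' against overlap with siblings, so summed profile areas never exceed the
#' cell profile area. Cells whose section plane misses every organelle
#' still contribute a cell profile with organelle area 0.
#'
#' @param cfg A [sphere_slice_config()].
#' @return List with `dataset` (data frame: cell_id, u = cell profile
#'   area, v = summed organelle profile area), `profiles` (data frame:
#'   cell_id, D1, D2 organelle profile diameters), `true_volume_fraction`,
#'   `true_surface_to_volume` and `k` (number of sectioned cells).
#' @export
slice_spheres <- function(cfg = sphere_slice_config()) {
  stopifnot(inherits(cfg, "sphere_slice_config"))
  withr::with_seed(cfg$seed, {
    R <- rlnorm_mean_cv(cfg$n_cells, cfg$cell_radius_mean,
                        cfg$cell_radius_cv)
    n_org <- stats::rpois(cfg$n_cells, cfg$organelle_count_mean)

    org_cell <- rep.int(seq_len(cfg$n_cells), n_org)
    n_tot <- length(org_cell)
    r_org <- rlnorm_mean_cv(n_tot, cfg$organelle_radius_mean,
                            cfg$organelle_radius_cv)
    r_org <- pmin(r_org, 0.9 * R[org_cell])
    # uniform placement inside the cell, rejecting organelle overlap;
    # organelles of one cell are contiguous in org_cell
    first_of_cell <- c(1L, 1L + cumsum(n_org))[org_cell]
    ox <- numeric(n_tot); oy <- numeric(n_tot); oz <- numeric(n_tot)
    for (j in seq_len(n_tot)) {
      sibs <- if (j > first_of_cell[j]) first_of_cell[j]:(j - 1L) else integer()
      rmax <- R[org_cell[j]] - r_org[j]
      for (try in 1:200) {
        u <- stats::rnorm(3)
        pos <- u / sqrt(sum(u^2)) * rmax * stats::runif(1)^(1 / 3)
        if (!length(sibs) ||
            all(sqrt((ox[sibs] - pos[1])^2 + (oy[sibs] - pos[2])^2 +
                     (oz[sibs] - pos[3])^2) >= r_org[sibs] + r_org[j])) {
          ox[j] <- pos[1]; oy[j] <- pos[2]; oz[j] <- pos[3]
          break
        }
        if (try == 200) { ox[j] <- pos[1]; oy[j] <- pos[2]; oz[j] <- pos[3] }
      }
    }

    # section: hit probability ~ R, plane offset uniform over (-R, R)
    hit <- stats::runif(cfg$n_cells) < R / max(R)
    h <- stats::runif(cfg$n_cells, -R, R)
  })

  idx <- which(hit)
  u <- pi * (R[idx]^2 - h[idx]^2)
  v <- numeric(length(idx))
  prof <- list()
  for (m in seq_along(idx)) {
    i <- idx[m]
    orgs <- which(org_cell == i)
    if (!length(orgs)) next
    dz <- abs(h[i] - oz[orgs])
    cut <- which(dz < r_org[orgs])
    if (!length(cut)) next
    rho <- sqrt(r_org[orgs][cut]^2 - dz[cut]^2)
    v[m] <- sum(pi * rho^2)
    prof[[length(prof) + 1L]] <-
      data.frame(cell_id = i, D1 = 2 * rho, D2 = 2 * rho)
  }

  vol_org <- (4 / 3) * pi * r_org^3
  vol_cell <- (4 / 3) * pi * R^3
  list(
    dataset = data.frame(cell_id = idx, u = u, v = v),
    profiles = if (length(prof)) do.call(rbind, prof) else
      data.frame(cell_id = integer(), D1 = numeric(), D2 = numeric()),
    true_volume_fraction = sum(vol_org) / sum(vol_cell),
    true_surface_to_volume = if (n_tot) {
      sum(4 * pi * r_org^2) / sum(vol_org)
    } else NA_real_,
    k = length(idx)
  )
}
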