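# Shared fixture builders: all synthetic, generated at test time.

# class map with disks of a given class drawn on background
make_disk_map <- function(dim_rc, centers_xy, radii, class = 1L) {
  m <- matrix(0L, dim_rc[1L], dim_rc[2L])
  for (i in seq_len(nrow(centers_xy))) {
    rows <- seq_len(dim_rc[1L])
    cols <- seq_len(dim_rc[2L])
    d <- sqrt(outer((rows - 1 - centers_xy[i, 2L])^2,
                    (cols - 1 - centers_xy[i, 1L])^2, `+`))
    m[d <= radii[i]] <- as.integer(class)
  }
  m
}

# segmentation params for fixture-scale maps: 1 px = 50 nm so a disk of
# radius 40 px (~12.6 um^2) passes the default area gate
fixture_params <- function(...) {
  segmentation_params(pixel_size_nm = 50, smoothing_radius_px = 0,
                      marker_separation_um = 1.5, ...)
}

# match detected cells to generator truth by nearest EM centroid
match_truth <- function(cells, truth) {
  vapply(seq_len(nrow(cells)), function(i) {
    which.min((truth$em_x - cells$x[i])^2 + (truth$em_y - cells$y[i])^2)
  }, 0L)
}

# small rendered sample reused across tests (computed once per run)
small_sample <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- render_sample(channel_panel(c("R", "G", "B")),
                              n_per_pattern = 2, seed = 42,
                              geometry = sample_geometry(lm_size = 400))
    }
    cache
  }
})

# measurement_masks object built by hand from explicit pixel coordinates
manual_masks <- function(dim_rc, pixel_list) {
  masks <- lapply(seq_along(pixel_list), function(i) {
    px <- pixel_list[[i]]       # cbind(row1, col1), 1-based
    list(id = i, idx = (px[, 2L] - 1L) * dim_rc[1L] + px[, 1L],
         flag = "ok")
  })
  structure(list(dim = dim_rc, masks = masks), class = "measurement_masks")
}

# arc length of an ellipse with semi-axes a >= b by adaptive quadrature of
# the arc-length integral: 4 a E(e) -- independent of the Ramanujan formula
ellipse_perimeter_quadrature <- function(D1, D2) {
  a <- max(D1, D2) / 2
  b <- min(D1, D2) / 2
  e2 <- 1 - (b / a)^2
  4 * a * stats::integrate(function(t) sqrt(1 - e2 * sin(t)^2), 0, pi / 2,
                           rel.tol = 1e-12)$value
}

# minimal Navigator autodoc text with one map and one point item
minimal_nav_lines <- function() {
  c("AdocVersion = 2.00",
    "",
    "[Item = map1]",
    "Type = 2",
    "StageXYZ = 12.5 -30.25 5",
    "RawStageXY = 12.5 -30.25",
    "MapWidthHeight = 200 100",
    "MapScaleMat = 0.02 0 0 0.02",
    "MapID = 77",
    "Regis = 1",
    "FooBar = 3",
    "",
    "[Item = pt1]",
    "Type = 0",
    "StageXYZ = 1.5 2.25 0",
    "Acquire = 1")
}
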