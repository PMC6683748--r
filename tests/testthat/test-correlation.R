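test_that("identical point sets fit to the identity with zero residuals", {
  src <- cbind(c(0, 10, 0, 7), c(0, 0, 10, 3))
  fit <- fit_affine(src, src)
  expect_equal(fit$transform$A, diag(2))
  expect_equal(fit$transform$b, c(0, 0))
  expect_equal(fit$residuals, rep(0, 4))
})

test_that("a noiseless similarity is recovered to 1e-9", {
  tf <- affine_similarity(8, 7, c(50, -20), direction = "em_to_lm")
  set.seed(1)
  src <- cbind(runif(8, 0, 2000), runif(8, 0, 2000))
  fit <- fit_affine(src, affine_apply(tf, src))
  expect_lt(max(abs(fit$transform$A - tf$A)), 1e-9)
  expect_lt(max(abs(fit$transform$b - tf$b)), 1e-9)
  expect_lt(fit$rms, 1e-9)
})

test_that("underdetermined or collinear control points are rejected", {
  expect_error(fit_affine(cbind(1:2, 1:2), cbind(1:2, 1:2)), "at least 3")
  line <- cbind(1:5, 2 * (1:5))
  expect_error(fit_affine(line, line), "collinear")
})

test_that("forward and inverse transforms compose to the identity", {
  set.seed(7)
  for (i in 1:5) {
    A <- matrix(rnorm(4, sd = 3), 2)
    if (abs(det(A)) < 1e-3) next
    tf <- affine2d(A, rnorm(2, sd = 50))
    pts <- cbind(runif(20, 0, 1000), runif(20, 0, 1000))
    back <- affine_apply(affine_invert(tf), affine_apply(tf, pts))
    expect_lt(max(abs(back - pts)), 1e-9)
  }
})

test_that("high residuals warn but do not fail", {
  set.seed(2)
  src <- cbind(runif(6, 0, 100), runif(6, 0, 100))
  dst <- src + matrix(rnorm(12, sd = 20), ncol = 2)
  expect_warning(fit_affine(src, dst), "rms residual")
})

test_that("filled masks reproduce the detected object at zero dilation", {
  cm <- make_disk_map(c(128, 128), cbind(64, 64), 40)
  cells <- detect_cells(cm, fixture_params())
  ident <- affine2d(diag(2), c(0, 0), direction = "em_to_lm")
  masks <- build_masks(cells, NULL, ident, c(128, 128), dilation_um = 0,
                       style = "filled")
  expect_equal(length(masks$masks), 1L)
  got <- masks$masks[[1L]]$idx
  obj <- which(cm == 1L)
  # the filled traced outline matches the object up to boundary
  # rasterization: same area within 3%, every mask pixel within 1 px of
  # the object
  expect_lt(abs(length(got) - length(obj)) / length(obj), 0.03)
  expect_gt(length(intersect(got, obj)) / length(obj), 0.97)
  rows0 <- (got - 1L) %% 128L
  cols0 <- (got - 1L) %/% 128L
  d <- sqrt((cols0 - 64)^2 + (rows0 - 64)^2)
  expect_lt(max(d), 41.5)
})

test_that("band masks hug the outline and overlap removal keeps masks disjoint", {
  centers <- cbind(c(60, 150), c(60, 60))
  cm <- make_disk_map(c(210, 210), centers, c(40, 40))
  cells <- detect_cells(cm, fixture_params())
  ident <- affine2d(diag(2), c(0, 0), direction = "em_to_lm")
  # large dilation so the two bands would overlap between the cells
  masks <- build_masks(cells, NULL, ident, c(210, 210), dilation_um = 0.3,
                       lm_pixel_size_um = 0.01)
  idx1 <- masks$masks[[1L]]$idx
  idx2 <- masks$masks[[2L]]$idx
  expect_gt(length(idx1), 0)
  expect_length(intersect(idx1, idx2), 0)
  # band excludes the deep interior of the cell
  rows0 <- (idx1 - 1L) %% 210L
  cols0 <- (idx1 - 1L) %/% 210L
  d <- sqrt((cols0 - 60)^2 + (rows0 - 60)^2)
  expect_gt(min(d), 5)
})

test_that("cells mapping outside the LM frame are excluded with empty masks", {
  cm <- make_disk_map(c(128, 128), cbind(64, 64), 40)
  cells <- detect_cells(cm, fixture_params())
  away <- affine2d(diag(2), c(5000, 5000), direction = "em_to_lm")
  masks <- build_masks(cells, NULL, away, c(128, 128))
  expect_equal(masks$masks[[1L]]$flag, "excluded_outside")
  expect_length(masks$masks[[1L]]$idx, 0)
  tab <- measure_intensities(array(1, c(128, 128, 2)), masks)
  expect_true(all(is.na(tab[1, c("ch1", "ch2")])))
  expect_equal(tab$flag, "excluded_outside")
})

test_that("masks cover the stained ring of every truth cell at default dilation", {
  s <- small_sample()
  cells <- detect_cells(s$class_map, segmentation_params())
  masks <- build_masks(cells, holes_mask(s$class_map),
                       affine_invert(s$lm_to_em), dim(s$lm_stack)[1:2])
  nr <- masks$dim[1L]
  nn <- match_truth(cells[cells$flags == "ok", ], s$truth)
  for (m in seq_along(masks$masks)) {
    tr <- s$truth[nn[m], ]
    rows <- seq_len(nr) - 1
    d <- sqrt(outer((rows - tr$lm_y)^2, (rows - tr$lm_x)^2, `+`))
    ring_idx <- which(d >= tr$radius_lm_px &
                        d <= tr$radius_lm_px + s$geometry$ring_px)
    covered <- mean(ring_idx %in% masks$masks[[m]]$idx)
    expect_gte(covered, 0.95)
  }
})

test_that("median measurement follows its definition", {
  img <- array(7, c(20, 20, 2))
  masks <- manual_masks(c(20, 20), list(cbind(c(2, 5, 9), c(3, 3, 4))))
  tab <- measure_intensities(img, masks)
  expect_equal(tab$ch1, 7)
  expect_equal(tab$n_px, 3L)
  img2 <- array(0, c(20, 20, 1))
  img2[cbind(c(2, 5, 9), c(3, 3, 4), 1)] <- c(1, 2, 100)
  tab2 <- measure_intensities(img2, masks)
  expect_equal(tab2$ch1, 2)
})

test_that("noiseless rendered medians equal brightness x bit + background exactly", {
  panel <- channel_panel(c("R", "G", "B"))
  s <- render_sample(panel, n_per_pattern = 2, seed = 3,
                     noise = noise_config(pixel_sd = 0, channel_cv = 0),
                     geometry = sample_geometry(lm_size = 400))
  cells <- detect_cells(s$class_map, segmentation_params())
  masks <- build_masks(cells, holes_mask(s$class_map),
                       affine_invert(s$lm_to_em), dim(s$lm_stack)[1:2])
  tab <- measure_intensities(s$lm_stack, masks, panel$names)
  ok <- cells[cells$flags == "ok", ]
  nn <- match_truth(ok, s$truth)
  expect_equal(as.matrix(tab[panel$names]),
               unname(s$ring_intensity[nn, , drop = FALSE]),
               ignore_attr = TRUE)
})
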