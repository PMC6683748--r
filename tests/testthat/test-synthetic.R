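test_that("rendering is a pure function of (config, seed)", {
  panel <- channel_panel(c("R", "G"))
  a <- render_sample(panel, n_per_pattern = 2, seed = 9,
                     geometry = sample_geometry(lm_size = 350))
  b <- render_sample(panel, n_per_pattern = 2, seed = 9,
                     geometry = sample_geometry(lm_size = 350))
  expect_identical(a$lm_stack, b$lm_stack)
  expect_identical(a$em_overview, b$em_overview)
  expect_identical(a$class_map, b$class_map)
  expect_identical(a$truth, b$truth)
  c <- render_sample(panel, n_per_pattern = 2, seed = 10,
                     geometry = sample_geometry(lm_size = 350))
  expect_false(identical(a$lm_stack, c$lm_stack))
})

test_that("noiseless single-cell ring carries brightness + background in stained channels only", {
  panel <- channel_panel(c("c1", "c2", "c3"))
  s <- render_sample(panel, patterns = list("100"), n_per_pattern = 1,
                     noise = noise_config(pixel_sd = 0, channel_cv = 0),
                     geometry = sample_geometry(lm_size = 150), seed = 4)
  tr <- s$truth
  rows <- seq_len(nrow(s$lm_stack)) - 1
  cols <- seq_len(ncol(s$lm_stack)) - 1
  d <- sqrt(outer((rows - tr$lm_y)^2, (cols - tr$lm_x)^2, `+`))
  ring <- d >= tr$radius_lm_px & d <= tr$radius_lm_px +
    s$geometry$ring_px
  bg <- s$noise$background
  expect_equal(unique(as.vector(s$lm_stack[, , 1L][ring])),
               tr$brightness + bg)
  expect_equal(unique(as.vector(s$lm_stack[, , 2L][ring])), bg)
  expect_equal(unique(as.vector(s$lm_stack[, , 3L][ring])), bg)
  # interior and exterior stay at background in every channel
  expect_equal(unique(as.vector(s$lm_stack[, , 1L][!ring])), bg)
})

test_that("overcrowded placement requests are refused", {
  panel <- channel_panel(c("R", "G", "B"))
  expect_error(
    render_sample(panel, n_per_pattern = 10, seed = 1,
                  geometry = sample_geometry(lm_size = 200,
                                             max_place_tries = 50)),
    "without overlap")
})

test_that("simulated intensity tables are reproducible and complete", {
  panel <- channel_panel(c("b", "g", "o", "f"))
  a <- simulate_intensities(panel, n_per_pattern = 10, seed = 3)
  b <- simulate_intensities(panel, n_per_pattern = 10, seed = 3)
  expect_identical(a, b)
  expect_equal(nrow(a$intensities), 15 * 10)
  expect_true(all(panel$names %in% names(a$intensities)))
  expect_true(all(as.matrix(a$intensities[panel$names]) >= 0))
  expect_equal(sort(unique(a$truth$pattern)),
               sort(vapply(enumerate_patterns(panel), attr, "",
                           which = "label")))
})

test_that("a written sample round-trips through the TIFF/CSV files", {
  s <- small_sample()
  dir <- withr::local_tempdir()
  write_sample(s, dir)
  lm <- read_lm_stack(file.path(dir, "lm.tif"))
  expect_equal(dim(lm), dim(s$lm_stack))
  # float32 storage: relative error at the 1e-7 scale
  expect_lt(max(abs(lm - s$lm_stack)) / max(s$lm_stack), 1e-6)
  cm <- read_class_map(file.path(dir, "class_map.tif"))
  expect_identical(cm, s$class_map)
  tf <- read_affine(file.path(dir, "lm_to_em.txt"))
  expect_equal(tf$A, s$lm_to_em$A)
  expect_equal(tf$b, s$lm_to_em$b)
  cp <- read_control_points(file.path(dir, "control_points.csv"))
  expect_equal(nrow(cp), 6)
})

test_that("sphere slicing with no organelles yields zero areas and zero truth", {
  sl <- slice_spheres(sphere_slice_config(n_cells = 200,
                                          organelle_count_mean = 0,
                                          seed = 2))
  expect_true(all(sl$dataset$v == 0))
  expect_equal(sl$true_volume_fraction, 0)
  expect_equal(nrow(sl$profiles), 0)
})

test_that("mean profile area of a sliced sphere approaches (2/3) pi R^2", {
  R <- 2
  sl <- slice_spheres(sphere_slice_config(n_cells = 20000,
                                          cell_radius_mean = R,
                                          cell_radius_cv = 0,
                                          organelle_count_mean = 0,
                                          seed = 5))
  analytic <- 2 / 3 * pi * R^2   # mean of pi (R^2 - h^2), h ~ U(-R, R)
  tol <- 3 * stats::sd(sl$dataset$u) / sqrt(nrow(sl$dataset))
  expect_lt(abs(mean(sl$dataset$u) - analytic), tol)
})

test_that("organelle profile areas never exceed the cell profile area", {
  for (seed in 1:3) {
    sl <- slice_spheres(sphere_slice_config(n_cells = 300,
                                            organelle_count_mean = 3,
                                            seed = seed))
    expect_true(all(sl$dataset$v >= 0))
    expect_true(all(sl$dataset$v <= sl$dataset$u))
    with_org <- sl$dataset$v > 0
    expect_true(all(sl$dataset$v[with_org] > 0))
    # profiles table is consistent with the per-cell sums
    by_cell <- tapply(ellipse_area(sl$profiles$D1, sl$profiles$D2),
                      sl$profiles$cell_id, sum)
    expect_equal(as.numeric(by_cell),
                 sl$dataset$v[match(as.integer(names(by_cell)),
                                    sl$dataset$cell_id)])
  }
})
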