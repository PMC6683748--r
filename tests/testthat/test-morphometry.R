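test_that("ellipse area follows pi D1 D2 / 4", {
  expect_equal(ellipse_area(2, 2), pi)
  expect_equal(ellipse_area(200, 100), 5000 * pi)
  expect_error(ellipse_area(1, 0), "positive")
  expect_error(ellipse_area(-2, 3), "positive")
})

test_that("Ramanujan circumference is exact for circles and symmetric", {
  expect_equal(ellipse_circumference(2, 2), 2 * pi, tolerance = 1e-12)
  r <- c(0.3, 1, 57.5)
  expect_equal(ellipse_circumference(2 * r, 2 * r), 2 * pi * r,
               tolerance = 1e-12)
  expect_equal(ellipse_circumference(4, 2), ellipse_circumference(2, 4))
})

test_that("Ramanujan circumference tracks the arc-length quadrature oracle", {
  for (aspect in c(1.1, 1.5, 2, 3, 4, 5)) {
    for (D2 in c(50, 300)) {
      D1 <- aspect * D2
      got <- ellipse_circumference(D1, D2)
      want <- ellipse_perimeter_quadrature(D1, D2)
      expect_lt(abs(got - want) / want, 0.002)
    }
  }
})

test_that("volume fraction is the ratio of summed areas", {
  expect_equal(volume_fraction(100, 5), 0.05)
  expect_equal(volume_fraction(c(10, 20, 30), c(0, 0, 0)), 0)
  expect_error(volume_fraction(numeric(), numeric()), "empty")
  expect_error(volume_fraction(c(10, -1), c(0, 0)), "positive")
  expect_error(volume_fraction(10, 11), "exceeds")
})

test_that("the ratio-estimator SE vanishes for proportional data and is scale invariant", {
  set.seed(4)
  u <- runif(50, 50, 150)
  expect_equal(volume_fraction_se(u, 0.07 * u), 0)
  v <- u * runif(50, 0.01, 0.1)
  se <- volume_fraction_se(u, v)
  expect_gt(se, 0)
  expect_equal(volume_fraction_se(2 * u, 2 * v), se, tolerance = 1e-12)
  expect_equal(volume_fraction(2 * u, 2 * v), volume_fraction(u, v))
  expect_error(volume_fraction_se(u[1], v[1]), "at least 2")
})

test_that("the SE formula agrees with a bootstrap of the ratio", {
  sl <- slice_spheres(sphere_slice_config(n_cells = 230, seed = 7))
  u <- sl$dataset$u
  v <- sl$dataset$v
  k <- length(u)
  expect_gte(k, 100)
  set.seed(1)
  boot <- replicate(2000, {
    i <- sample.int(k, k, replace = TRUE)
    sum(v[i]) / sum(u[i])
  })
  se <- volume_fraction_se(u, v)
  expect_lt(abs(se - stats::sd(boot)) / stats::sd(boot), 0.25)
})

test_that("SE shrinks roughly as 1/sqrt(k) on homogeneous data", {
  big <- slice_spheres(sphere_slice_config(n_cells = 8000, seed = 3))
  u <- big$dataset$u
  v <- big$dataset$v
  se_small <- volume_fraction_se(u[1:500], v[1:500])
  se_big <- volume_fraction_se(u, v)
  ratio <- se_small / se_big
  expect_gt(ratio, sqrt(length(u) / 500) * 0.6)
  expect_lt(ratio, sqrt(length(u) / 500) * 1.6)
})

test_that("surface-to-volume has the circle closed form and scales as 1/length", {
  R <- 3
  A <- ellipse_area(2 * R, 2 * R)
  C <- ellipse_circumference(2 * R, 2 * R)
  expect_equal(surface_to_volume(A, C), 8 / (pi * R))
  expect_equal(surface_to_volume(A, C, include_constant = FALSE),
               (2 * pi * R) / (pi * R^2))
  # scaling every diameter by s scales the estimate by 1/s
  prof <- data.frame(cell_id = 1:4, D1 = c(4, 6, 3, 5), D2 = c(2, 5, 3, 4))
  p1 <- read_profiles(prof)
  s <- 2.5
  p2 <- read_profiles(transform(prof, D1 = D1 * s, D2 = D2 * s))
  expect_equal(surface_to_volume(p2$A, p2$C),
               surface_to_volume(p1$A, p1$C) / s)
  expect_error(surface_to_volume(numeric(), numeric()), "at least one")
})

test_that("sliced sphere populations recover the true 3/r surface-to-volume", {
  sl <- slice_spheres(sphere_slice_config(n_cells = 20000,
                                          organelle_count_mean = 2,
                                          organelle_radius_cv = 0,
                                          seed = 9))
  est <- surface_to_volume(ellipse_area(sl$profiles$D1, sl$profiles$D2),
                           ellipse_circumference(sl$profiles$D1,
                                                 sl$profiles$D2))
  expect_lt(abs(est - sl$true_surface_to_volume) /
              sl$true_surface_to_volume, 0.05)
})

test_that("group summaries join measurements to barcode calls", {
  areas <- data.frame(cell_id = 1:6, area = c(100, 120, 80, 100, 90, 110))
  prof <- data.frame(cell_id = c(1, 1, 3, 5), D1 = c(4, 3, 5, 6),
                     D2 = c(4, 3, 5, 4))
  calls <- data.frame(id = 1:6, cluster = 0L,
                      pattern = rep(c("01", "10"), each = 3),
                      distance = 0, flags = "ok")
  out <- summarize_groups(areas, prof, calls)
  expect_equal(out$group, c("01", "10"))
  expect_equal(out$k, c(3L, 3L))
  p <- read_profiles(prof)
  expect_equal(out$V_r[1L], sum(p$A[p$cell_id <= 3]) / sum(100, 120, 80))
  # identical data in two groups gives identical summaries
  areas2 <- data.frame(cell_id = 1:4, area = 100,
                       group = rep(c("a", "b"), each = 2))
  prof2 <- data.frame(cell_id = c(1, 3), D1 = 2, D2 = 2,
                      group = c("a", "b"))
  out2 <- summarize_groups(areas2, read_profiles(prof2))
  expect_equal(out2$V_r[1L], out2$V_r[2L])
  expect_equal(out2$S_V[1L], out2$S_V[2L])
  # single unlabeled group equals the global computation
  out3 <- summarize_groups(areas, prof)
  expect_equal(out3$V_r, volume_fraction(areas$area, c(
    sum(p$A[p$cell_id == 1]), 0, p$A[p$cell_id == 3][1], 0,
    p$A[p$cell_id == 5][1], 0)))
})

test_that("orphan measurement ids are reported", {
  areas <- data.frame(cell_id = 1:3, area = 100)
  calls <- data.frame(id = 1:2, cluster = 0L, pattern = "1",
                      distance = 0, flags = "ok")
  expect_error(summarize_groups(areas, NULL, calls), "without a barcode")
  prof <- data.frame(cell_id = 9, D1 = 2, D2 = 2)
  expect_error(summarize_groups(areas, prof), "without a measured")
})
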