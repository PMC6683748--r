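panel3 <- channel_panel(c("R", "G", "B"))

test_that("channel normalization matches the (x - min) / IQR convention", {
  tab <- data.frame(id = 1:5, R = c(10, 20, 30, 40, 50),
                    G = c(5, 6, 7, 8, 9), B = c(1, 2, 3, 4, 100))
  norm <- normalize_channels(tab, panel3)
  # quartiles by linear interpolation: Q1 = 20, Q3 = 40
  expect_equal(unname(norm$N[, "R"]), c(0, 0.5, 1.0, 1.5, 2.0))
  expect_equal(norm$meta$min[1L], 10)
  expect_equal(norm$meta$q1[1L], 20)
  expect_equal(norm$meta$q3[1L], 40)
  # the argmin cell lands exactly at zero in each channel
  expect_true(all(apply(norm$N, 2L, min) == 0))
})

test_that("channel normalization is invariant to affine rescaling of a channel", {
  set.seed(3)
  tab <- data.frame(id = 1:40, R = runif(40, 10, 200),
                    G = runif(40, 5, 80), B = runif(40, 0, 30))
  a <- normalize_channels(tab, panel3)
  tab2 <- tab
  tab2$G <- 3.7 * tab$G + 11
  b <- normalize_channels(tab2, panel3)
  expect_equal(a$N, b$N, tolerance = 1e-12)
})

test_that("uninformative channels are reported by name", {
  tab <- data.frame(id = 1:6, R = 1:6, G = rep(2, 6), B = 1:6)
  expect_error(normalize_channels(tab, panel3), "'G'")
  expect_error(normalize_channels(tab[1:3, ], panel3), "at least 4")
})

test_that("per-cell normalization scales each classifiable row to max 1", {
  norm <- list(N = rbind(c(2, 0.5, 1), c(0, 0, 0), c(0.2, 0.8, 0.4)),
               ids = 1:3)
  fin <- normalize_per_cell(norm)
  expect_equal(fin$F_mat[1L, ], c(1, 0.25, 0.5))
  expect_equal(fin$unclassifiable_ids, 2L)
  expect_true(all(abs(apply(fin$F_mat, 1L, max) - 1) < 1e-12))
})

test_that("k-means recovers pure clusters from ideal pattern vectors", {
  pats <- enumerate_patterns(panel3)
  ideal <- do.call(rbind, lapply(pats, as.numeric))
  F_mat <- ideal[rep(seq_len(7), each = 50), ]
  cl <- cluster_barcodes(F_mat, k = 7, seed = 5)
  truth <- rep(seq_len(7), each = 50)
  purity <- mean(vapply(split(truth, cl$labels), function(g) {
    max(table(g)) / length(g)
  }, 0))
  expect_equal(purity, 1)
  expect_equal(cl$tot_withinss, 0)
})

test_that("k = 1 returns a single cluster centred on the mean", {
  set.seed(2)
  F_mat <- matrix(runif(60), 20)
  cl <- cluster_barcodes(F_mat, k = 1, seed = 1)
  expect_true(all(cl$labels == 0L))
  expect_equal(unname(cl$centroids[1L, ]), unname(colMeans(F_mat)))
  expect_error(cluster_barcodes(F_mat, k = 21, seed = 1), "exceeds")
})

test_that("the Hungarian matching agrees with brute-force enumeration", {
  all_perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    do.call(c, lapply(seq_along(v), function(i) {
      lapply(all_perms(v[-i]), function(r) c(v[i], r))
    }))
  }
  set.seed(11)
  for (k in c(3, 5, 6)) {
    cost <- matrix(runif(k * k), k)
    got <- clemux:::solve_assignment(cost)
    best <- Inf
    for (pm in all_perms(seq_len(k))) {
      best <- min(best, sum(cost[cbind(seq_len(k), pm)]))
    }
    expect_equal(sum(cost[cbind(seq_len(k), got)]), best)
    expect_equal(sort(got), seq_len(k))   # a permutation
  }
})

test_that("cluster identities are assigned to the nearest ideal patterns", {
  pats <- enumerate_patterns(panel3)
  ideal <- do.call(rbind, lapply(pats, as.numeric))
  expect_equal(assign_cluster_identities(ideal, pats), seq_len(7))
  # perturbations below half the minimum ideal-ideal distance keep the map
  min_d <- min(dist(ideal))
  set.seed(8)
  pert <- ideal + matrix(runif(21, -1, 1), 7) * (0.4 * min_d / sqrt(3))
  expect_equal(assign_cluster_identities(pert, pats), seq_len(7))
  # permuting the centroid list permutes the assignment identically
  ord <- sample(7)
  expect_equal(assign_cluster_identities(pert[ord, ], pats),
               seq_len(7)[ord])
  expect_error(assign_cluster_identities(ideal[1:3, ], pats), "differs")
})

test_that("noiseless classification is perfect and zero cells are flagged", {
  panel <- channel_panel(c("b", "g", "o", "f"))
  sim <- simulate_intensities(panel, n_per_pattern = 20,
                              noise = noise_config(brightness_sdlog = 0.3,
                                                   channel_cv = 0,
                                                   pixel_sd = 0),
                              seed = 21)
  calls <- classify_cells(sim$intensities, panel, seed = 21)
  expect_equal(mean(calls$pattern == sim$truth$pattern), 1)
  # inject all-zero cells: flagged unclassifiable, others unchanged
  tab <- sim$intensities
  zeros <- tab[1:5, ]
  zeros$id <- 1000 + 1:5
  zeros[panel$names] <- 0
  calls2 <- classify_cells(rbind(tab, zeros), panel, seed = 21)
  expect_true(all(calls2$flags[calls2$id > 1000] == "unclassifiable"))
  kept <- calls2[calls2$id <= 1000, ]
  expect_equal(mean(kept$pattern == sim$truth$pattern), 1)
})

test_that("calls are equivariant to channel rescaling and row order", {
  panel <- channel_panel(c("b", "g", "o"))
  sim <- simulate_intensities(panel, n_per_pattern = 30, seed = 13)
  base <- classify_cells(sim$intensities, panel, seed = 2)
  resc <- sim$intensities
  resc$g <- 5 * resc$g + 40
  resc$o <- 0.3 * resc$o + 2
  again <- classify_cells(resc, panel, seed = 2)
  expect_equal(again$pattern, base$pattern)
  shuf <- sim$intensities[sample(nrow(sim$intensities)), ]
  shuffled <- classify_cells(shuf, panel, seed = 2)
  m <- match(base$id, shuffled$id)
  expect_equal(shuffled$pattern[m], base$pattern)
})

test_that("manual overrides exclude and reassign cells", {
  calls <- data.frame(id = 1:4, cluster = c(0L, 1L, 0L, 1L),
                      pattern = c("01", "10", "01", "10"),
                      distance = 0.1, flags = "ok")
  ov <- data.frame(id = c(2, 4), action = c("exclude", "reassign:11"))
  out <- apply_overrides(calls, ov)
  expect_equal(out$flags[2L], "excluded,manual_override")
  expect_equal(out$pattern[4L], "11")
  expect_equal(out$flags[4L], "manual_override")
  expect_error(apply_overrides(calls, data.frame(id = 99,
                                                 action = "exclude")),
               "unknown cell id")
  expect_error(apply_overrides(calls, data.frame(id = 1,
                                                 action = "promote")),
               "unknown override action")
})

test_that("qc report writes one thumbnail and one CSV row per cell, deterministically", {
  s <- small_sample()
  cells <- detect_cells(s$class_map, segmentation_params())
  masks <- build_masks(cells, holes_mask(s$class_map),
                       affine_invert(s$lm_to_em), dim(s$lm_stack)[1:2])
  tab <- measure_intensities(s$lm_stack, masks, s$panel$names)
  calls <- classify_cells(tab, s$panel, seed = 1)
  dir1 <- withr::local_tempdir()
  qc_report(calls, cells, s$lm_stack, masks, s$em_overview, dir1)
  written <- utils::read.csv(file.path(dir1, "calls.csv"))
  expect_equal(nrow(written), nrow(calls))
  pngs <- list.files(file.path(dir1, "thumbnails"), recursive = TRUE,
                     pattern = "\\.png$")
  expect_equal(length(pngs), sum(calls$flags != "unclassifiable"))
  dir2 <- withr::local_tempdir()
  qc_report(calls, cells, s$lm_stack, masks, s$em_overview, dir2)
  expect_identical(readBin(file.path(dir1, "calls.csv"), "raw", 1e6),
                   readBin(file.path(dir2, "calls.csv"), "raw", 1e6))
  # override CSV excludes two cells in the final table
  ov <- file.path(dir2, "ov.csv")
  utils::write.csv(data.frame(id = calls$id[1:2], action = "exclude"),
                   ov, row.names = FALSE)
  final <- qc_report(calls, cells, s$lm_stack, masks, s$em_overview,
                     withr::local_tempdir(), overrides = ov,
                     thumbnails = FALSE)
  expect_equal(sum(grepl("excluded", final$flags)), 2L)
})
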