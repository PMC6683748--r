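#' Channel-wise (step 1) intensity normalization
#'
#' Brings all channels to comparable ranges: for each channel the minimum
#' observed raw median is subtracted and the result is divided by the
#' interquartile range of that channel across cells,
#' `N = (I - min(I)) / (Q3(I) - Q1(I))`. The IQR is used instead of the
#' min-max range because it characterizes the distribution shape without
#' depending on outliers. Quartiles use linear interpolation between order
#' statistics (R quantile type 7).
#'
#' @param table Intensity data frame with an `id` column and one column
#'   per channel ([measure_intensities()] output; extra columns such as
#'   `n_px`/`flag` are ignored). Rows with any missing channel value are
#'   excluded from normalization (and from the quantiles).
#' @param panel [channel_panel()] naming the channel columns.
#' @param min_prob Probability for the "minimum" reference; 0 (default)
#'   is the literal observed minimum, small positive values give a
#'   robust-percentile alternative.
#' @return List: `N` (cells x channels matrix), `ids`, `meta` (per-channel
#'   min/Q1/Q3), `excluded_ids` (rows with missing values).
#' @export
normalize_channels <- function(table, panel, min_prob = 0) {
  panel <- as_panel(panel)
  miss <- setdiff(panel$names, names(table))
  if (length(miss)) {
    stop("intensity table lacks channel columns: ",
         paste(miss, collapse = ", "))
  }
  raw <- as.matrix(table[panel$names])
  complete <- stats::complete.cases(raw)
  excluded <- table$id[!complete]
  raw <- raw[complete, , drop = FALSE]
  ids <- table$id[complete]
  if (nrow(raw) < 4L) {
    stop("channel normalization needs at least 4 cells with complete ",
         "measurements, got ", nrow(raw))
  }
  meta <- data.frame(channel = panel$names,
                     min = apply(raw, 2L, stats::quantile, probs = min_prob,
                                 type = 7, names = FALSE),
                     q1 = apply(raw, 2L, stats::quantile, probs = 0.25,
                                type = 7, names = FALSE),
                     q3 = apply(raw, 2L, stats::quantile, probs = 0.75,
                                type = 7, names = FALSE))
  iqr <- meta$q3 - meta$q1
  flat <- which(iqr <= 0)
  if (length(flat)) {
    stop("channel '", paste(panel$names[flat], collapse = "', '"),
         "' has zero interquartile range; it carries no information")
  }
  N <- sweep(sweep(raw, 2L, meta$min, `-`), 2L, iqr, `/`)
  list(N = N, ids = ids, meta = meta, excluded_ids = excluded)
}

#' Per-cell (step 2) intensity normalization
#'
#' Removes the per-cell total labelling level: each cell's channel values
#' are divided by its maximal channel value, `F = N / max(N)`, so every
#' classifiable cell has maximum exactly 1. Cells whose maximum is not
#' positive carry no usable signal and are flagged unclassifiable.
#'
#' @param norm Output of [normalize_channels()].
#' @return List: `F_mat` (cells x channels, rows scaled to max 1), `ids`,
#'   `unclassifiable_ids`.
#' @export
normalize_per_cell <- function(norm) {
  rmax <- apply(norm$N, 1L, max)
  bad <- rmax <= 0
  F_mat <- norm$N[!bad, , drop = FALSE] / rmax[!bad]
  list(F_mat = F_mat, ids = norm$ids[!bad],
       unclassifiable_ids = norm$ids[bad])
}

# k-means++ seeding: first center uniform, then proportional to squared
# distance from the nearest chosen center
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  centers[1L, ] <- x[sample.int(n, 1L), ]
  if (k > 1L) {
    d2 <- rowSums(sweep(x, 2L, centers[1L, ])^2)
    for (j in 2:k) {
      if (all(d2 <= 0)) {
        centers[j, ] <- x[sample.int(n, 1L), ]
      } else {
        centers[j, ] <- x[sample.int(n, 1L, prob = d2), ]
      }
      d2 <- pmin(d2, rowSums(sweep(x, 2L, centers[j, ])^2))
    }
  }
  centers
}

#' Cluster final normalized intensities by k-means
#'
#' Standard Euclidean k-means on the per-cell normalized intensity
#' vectors, with the number of clusters equal to the expected number of
#' color combinations. Initialization is k-means++ with a configurable
#' number of restarts; the best run by total within-cluster sum of
#' squares is kept. The seed is mandatory so runs are reproducible.
#'
#' @param F_mat Cells x channels matrix from [normalize_per_cell()].
#' @param k Number of clusters (expected number of barcode patterns).
#' @param seed Integer seed.
#' @param restarts Number of k-means++ restarts. Default 50.
#' @return List: `labels` (0-based cluster index per cell), `centroids`
#'   (k x channels), `tot_withinss`.
#' @export
cluster_barcodes <- function(F_mat, k, seed, restarts = 50) {
  F_mat <- as.matrix(F_mat)
  if (k < 1L) stop("k must be >= 1")
  if (k > nrow(F_mat)) {
    stop("k = ", k, " exceeds the number of classifiable cells (",
         nrow(F_mat), ")")
  }
  best <- NULL
  withr::with_seed(seed, {
    for (r in seq_len(restarts)) {
      centers <- kmeanspp_centers(F_mat, k)
      fit <- tryCatch(
        suppressWarnings(stats::kmeans(F_mat, centers = centers,
                                       iter.max = 100L)),
        error = function(e) NULL)
      if (is.null(fit)) next
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
  })
  if (is.null(best)) stop("k-means failed for every restart")
  list(labels = as.integer(best$cluster) - 1L, centroids = best$centers,
       tot_withinss = best$tot.withinss)
}

# Hungarian algorithm (shortest augmenting path with potentials), O(n^3).
# Returns, for each row of the square cost matrix, the assigned column.
solve_assignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  u <- numeric(n + 1L)            # row potentials, index i+1 for row i
  v <- numeric(n + 1L)            # column potentials, index j+1 for col j
  p <- integer(n + 1L)            # p[j+1] = row matched to column j
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1L)
    used <- logical(n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1L]) {
          cur <- cost[i0, j] - u[i0 + 1L] - v[j + 1L]
          if (cur < minv[j + 1L]) {
            minv[j + 1L] <- cur
            way[j + 1L] <- j0
          }
          if (minv[j + 1L] < delta) {
            delta <- minv[j + 1L]
            j1 <- j
          }
        }
      }
      for (j in 0:n) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assignment <- integer(n)
  for (j in seq_len(n)) {
    if (p[j + 1L] > 0L) assignment[p[j + 1L]] <- j
  }
  assignment
}

#' Map k-means clusters to barcode patterns
#'
#' Each pattern's ideal vector in final-normalized space is its bit vector
#' (the maximal channel of any nonzero pattern is 1, matching the row
#' normalization). Clusters are matched one-to-one to patterns by the
#' assignment minimizing the total Euclidean distance between centroids
#' and ideal vectors (Hungarian method). Ties are broken deterministically
#' by pattern binary order (patterns are scanned in that order).
#'
#' @param centroids k x channels matrix from [cluster_barcodes()].
#' @param patterns Patterns in use; must be exactly k patterns.
#' @return Integer vector: for cluster c (row c of `centroids`), the index
#'   into `patterns` of its assigned pattern.
#' @export
assign_cluster_identities <- function(centroids, patterns) {
  centroids <- as.matrix(centroids)
  k <- nrow(centroids)
  if (length(patterns) != k) {
    stop("number of centroids (", k, ") differs from number of patterns ",
         "in use (", length(patterns), ")")
  }
  ideal <- do.call(rbind, lapply(patterns, as.numeric))
  if (ncol(ideal) != ncol(centroids)) {
    stop("centroid dimensionality does not match the panel size")
  }
  cost <- outer(seq_len(k), seq_len(k), Vectorize(function(cc, pp) {
    sqrt(sum((centroids[cc, ] - ideal[pp, ])^2))
  }))
  solve_assignment(cost)
}

#' Classify cells into barcode patterns
#'
#' Full demultiplexing chain: channel-wise normalization, per-cell
#' normalization, k-means clustering in final-normalized space (k = number
#' of patterns in use), and Hungarian cluster-to-pattern matching. Cells
#' with no usable signal are flagged `unclassifiable`; cells far from
#' their cluster centroid (beyond a configurable quantile of
#' within-cluster distances) are flagged `low_confidence`.
#'
#' @inheritParams normalize_channels
#' @param patterns Patterns in use (list of bit vectors or label
#'   strings); defaults to all `2^n - 1` patterns of the panel.
#' @param seed Integer seed for clustering (mandatory).
#' @param restarts k-means++ restarts. Default 50.
#' @param low_conf_quantile Within-cluster distance quantile above which
#'   a call is flagged low confidence. Default 0.95.
#' @param min_prob Passed to [normalize_channels()].
#' @return A data frame of barcode calls: `id`, `cluster` (0-based, NA
#'   for unclassifiable), `pattern` (label string), `distance` (to own
#'   centroid in F-space), `flags`.
#' @export
classify_cells <- function(table, panel, patterns = NULL, seed = 1,
                           restarts = 50, low_conf_quantile = 0.95,
                           min_prob = 0) {
  panel <- as_panel(panel)
  if (is.null(patterns)) patterns <- enumerate_patterns(panel)
  patterns <- check_patterns(patterns, panel)
  labels <- vapply(patterns, attr, "", which = "label")

  norm <- normalize_channels(table, panel, min_prob = min_prob)
  fin <- normalize_per_cell(norm)
  k <- length(patterns)
  cl <- cluster_barcodes(fin$F_mat, k, seed = seed, restarts = restarts)
  pat_of_cluster <- assign_cluster_identities(cl$centroids, patterns)

  dist_own <- sqrt(rowSums((fin$F_mat -
                              cl$centroids[cl$labels + 1L, , drop = FALSE])^2))
  flags <- rep("ok", length(fin$ids))
  for (c0 in unique(cl$labels)) {
    sel <- cl$labels == c0
    thr <- stats::quantile(dist_own[sel], low_conf_quantile, type = 7,
                           names = FALSE)
    flags[sel & dist_own > thr] <- "low_confidence"
  }

  calls <- data.frame(
    id = fin$ids,
    cluster = cl$labels,
    pattern = labels[pat_of_cluster[cl$labels + 1L]],
    distance = dist_own,
    flags = flags)

  extra_ids <- c(fin$unclassifiable_ids, norm$excluded_ids)
  if (length(extra_ids)) {
    calls <- rbind(calls, data.frame(
      id = extra_ids, cluster = NA_integer_, pattern = NA_character_,
      distance = NA_real_, flags = "unclassifiable"))
  }
  calls <- calls[order(calls$id), , drop = FALSE]
  rownames(calls) <- NULL
  attr(calls, "centroids") <- cl$centroids
  attr(calls, "pattern_of_cluster") <- labels[pat_of_cluster]
  calls
}

#' Read a barcode calls CSV
#'
#' Reads a `calls.csv` written by [qc_report()] or the classify stage,
#' keeping the `pattern` column as character so barcode strings with
#' leading zeros (e.g. `"011"`) survive the round trip.
#'
#' @param path CSV path.
#' @return Data frame of calls.
#' @export
read_calls <- function(path) {
  utils::read.csv(path, colClasses = c(pattern = "character"))
}

#' Apply a manual override table to barcode calls
#'
#' Mirrors the interactive validation step non-interactively: an override
#' CSV with columns `id, action` either excludes a cell
#' (`action = "exclude"`) or reassigns its pattern
#' (`action = "reassign:<pattern>"`). Overridden cells are flagged
#' `manual_override` (excluded ones `excluded,manual_override`).
#'
#' @param calls Data frame from [classify_cells()].
#' @param overrides Data frame with columns `id`, `action`, or a CSV path.
#' @return The amended calls data frame.
#' @export
apply_overrides <- function(calls, overrides) {
  if (is.character(overrides)) overrides <- utils::read.csv(overrides)
  if (!all(c("id", "action") %in% names(overrides))) {
    stop("override table must have columns id, action")
  }
  for (r in seq_len(nrow(overrides))) {
    i <- which(calls$id == overrides$id[r])
    if (!length(i)) stop("override refers to unknown cell id ",
                         overrides$id[r])
    act <- overrides$action[r]
    if (act == "exclude") {
      calls$flags[i] <- "excluded,manual_override"
    } else if (startsWith(act, "reassign:")) {
      calls$pattern[i] <- sub("^reassign:", "", act)
      calls$flags[i] <- "manual_override"
    } else {
      stop("unknown override action '", act, "' for id ", overrides$id[r])
    }
  }
  calls
}

#' Write a quality-control report for barcode calls
#'
#' Writes `calls.csv` (id, cluster, pattern, distance, flags) and a
#' per-cell thumbnail gallery under `thumbnails/<pattern>/cell_<id>.png`,
#' each thumbnail showing the cell's crop in every LM channel followed by
#' the EM overview crop, so barcode assignment and EM preservation can be
#' assessed together. An optional override table is applied first.
#'
#' @param calls Data frame from [classify_cells()].
#' @param cells Data frame from [detect_cells()] (for EM crop locations).
#' @param lm_stack row x col x channel LM array.
#' @param masks `measurement_masks` from [build_masks()].
#' @param em_overview EM overview matrix.
#' @param out_dir Output directory.
#' @param overrides Optional override CSV path or data frame
#'   (see [apply_overrides()]).
#' @param thumbnails Set `FALSE` to skip the PNG gallery.
#' @return The final calls data frame, invisibly.
#' @export
qc_report <- function(calls, cells, lm_stack, masks, em_overview, out_dir,
                      overrides = NULL, thumbnails = TRUE) {
  if (is.null(lm_stack) || is.null(em_overview)) {
    stop("qc_report requires the LM stack and EM overview images")
  }
  if (!is.null(overrides)) calls <- apply_overrides(calls, overrides)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(calls, file.path(out_dir, "calls.csv"),
                   row.names = FALSE, quote = FALSE)
  if (!thumbnails) return(invisible(calls))

  if (length(dim(lm_stack)) == 2L) {
    lm_stack <- array(lm_stack, c(dim(lm_stack), 1L))
  }
  n_ch <- dim(lm_stack)[3L]
  nr <- masks$dim[1L]; nc <- masks$dim[2L]
  crop <- function(img, cx, cy, half) {
    r <- max(1L, round(cy) + 1L - half):min(nrow(img), round(cy) + 1L + half)
    c <- max(1L, round(cx) + 1L - half):min(ncol(img), round(cx) + 1L + half)
    img[r, c, drop = FALSE]
  }
  for (i in seq_len(nrow(calls))) {
    id <- calls$id[i]
    pat <- calls$pattern[i]
    m <- Find(function(mm) mm$id == id, masks$masks)
    if (is.null(m) || !length(m$idx)) next
    rows0 <- (m$idx - 1L) %% nr
    cols0 <- (m$idx - 1L) %/% nr
    cx <- mean(cols0); cy <- mean(rows0)
    half <- max(max(cols0) - min(cols0), max(rows0) - min(rows0)) %/% 2L + 4L
    ci <- cells[cells$id == id, , drop = FALSE]
    sub <- file.path(out_dir, "thumbnails",
                     if (is.na(pat)) "unclassified" else pat)
    dir.create(sub, showWarnings = FALSE, recursive = TRUE)
    grDevices::png(file.path(sub, sprintf("cell_%04d.png", id)),
                   width = 120 * (n_ch + 1L), height = 140)
    graphics::par(mfrow = c(1, n_ch + 1L), mar = c(0.5, 0.5, 1.5, 0.5))
    for (ch in seq_len(n_ch)) {
      cr <- crop(lm_stack[, , ch], cx, cy, half)
      graphics::image(t(cr)[, nrow(cr):1, drop = FALSE],
                      col = grDevices::gray.colors(256, 0, 1), axes = FALSE,
                      main = paste0("ch", ch), cex.main = 0.8)
    }
    if (nrow(ci)) {
      em_half <- max(8L, as.integer(sqrt(ci$area_px / pi) * 1.5))
      cr <- crop(em_overview, ci$x, ci$y, em_half)
      graphics::image(t(cr)[, nrow(cr):1, drop = FALSE],
                      col = grDevices::gray.colors(256, 0, 1), axes = FALSE,
                      main = "EM", cex.main = 0.8)
    } else {
      graphics::plot.new()
    }
    grDevices::dev.off()
  }
  invisible(calls)
}
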