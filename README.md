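# clemux

Demultiplexing combinatorial fluorescent barcodes in correlative
light-electron microscopy (CLEM).

## What this is for

Pooling many cell populations into a single EM block makes high-throughput
electron microscopy practical: prepare once, section once, image once. The
price is a demultiplexing problem — each population is stained with a
distinct *combination* of fluorophore conjugates on the cell wall (a
binary barcode over the fluorescent channels), and after imaging, every
cell profile in the EM overview must be traced back to its population of
origin from the registered light-microscopy signal. With `n` channels,
each present or absent and the all-absent combination excluded,
`2^n - 1` populations can be pooled: 7 with three dyes, 15 with four,
31 with five.

`clemux` is an R toolkit for the full computational pipeline:

* **`detect_cells()`** — watershed segmentation of cell profiles from a
  pixel-class map of the EM overview (cell / resin / hole / debris), with
  size, circularity and edge gating.
* **`fit_affine()`** — least-squares landmark registration between the LM
  and EM pixel frames.
* **`build_masks()` / `measure_intensities()`** — dilated outline-band
  measurement masks (overlaps and holes subtracted from every claimant),
  per-cell median intensity per channel.
* **`classify_cells()`** — two-step normalization
  `N = (I - min I) / IQR(I)` across cells, then `F = N / max N` per cell,
  k-means clustering in `F`-space with `k` = number of expected barcodes,
  and Hungarian matching of clusters to ideal bit-vector patterns.
* **`qc_report()`** — per-cell thumbnail galleries grouped by assigned
  barcode plus a calls CSV, with a non-interactive override table.
* **`read_navigator()` / `add_acquisition_points()`** — lossless SerialEM
  Navigator (autodoc) reading/writing and export of selected cell
  coordinates as acquisition points.
* **`volume_fraction()` / `surface_to_volume()`** — stereological
  organelle morphometry from measured profile ellipses: the Delesse ratio
  `V_r = Σv / Σu` with its ratio-estimator standard error, and
  `S/V = (4/π) ΣC / ΣA`.
* **`render_sample()` / `slice_spheres()`** — a ground-truthed synthetic
  generator (barcoded LM/EM image pairs with a known affine, and sliced
  3D sphere populations) standing in for the microscope.

See the methods vignette (`vignettes/clemux-methods.Rmd`) for the models,
conventions and design decisions.

## Worked example

A fully synthetic end-to-end run: simulate a pooled sample of 7 barcoded
populations (3 channels), detect cells in the EM frame, register, measure,
classify, and export acquisition points:

```r
library(clemux)

panel <- channel_panel(c("blue", "green", "orange"))
length(enumerate_patterns(panel))
#> [1] 7

cfg <- default_config()
cfg$channels <- c("blue", "green", "orange")
cfg$n_per_pattern <- 3
res <- run_pipeline("demo_run", cfg, seed = 1)
head(res$calls)
#>   id cluster pattern    distance          flags
#> 1  1       4     001 0.004142165             ok
#> 2  2       6     010 0.002588176 low_confidence
#> 3  3       2     111 0.070290839             ok
#> 4  4       0     110 0.077668097 low_confidence
#> 5  5       5     011 0.121306122 low_confidence
#> 6  6       1     101 0.135600447 low_confidence
```

All 21 simulated cells are recovered and every barcode call matches the
generator's ground truth (`demo_run/sim/truth.csv`); `low_confidence` is
an audit flag (distance above the 95th percentile of within-cluster
distances — with only 3 cells per cluster it flags roughly one cell per
cluster by construction). `demo_run/` now contains the detected cell
table, the fitted transform, the intensity table, QC galleries under
`qc/thumbnails/<pattern>/`, and `points.nav` with one acquisition point
per classified cell.

Stereology on a simulated population of organelle-bearing cells:

```r
sl <- slice_spheres(sphere_slice_config(n_cells = 10000, seed = 1))
vr <- volume_fraction(sl$dataset$u, sl$dataset$v)
se <- volume_fraction_se(sl$dataset$u, sl$dataset$v)
sprintf("V_r = %.5f +/- %.5f (true %.5f), k = %d",
        vr, se, sl$true_volume_fraction, sl$k)
#> [1] "V_r = 0.00301 +/- 0.00010 (true 0.00320), k = 6879"
```

The estimated organelle volume fraction sits within two standard errors of
the exact 3D fraction of the simulated population.

## Command line

A thin wrapper is installed with the package:

```sh
CLEMUX=$(Rscript -e 'cat(system.file("cli", "clemux", package = "clemux"))')
Rscript $CLEMUX pipeline --out run1 --seed 1
Rscript $CLEMUX morpho --cell-areas areas.csv --profiles profiles.csv \
        --calls run1/calls.csv --out summary.csv
```

Commands: `simulate`, `detect`, `correlate`, `classify`, `qc-report`,
`nav-export`, `morpho`, `pipeline`. `--config file.yaml` merges over
`default_config()`; every run writes a `manifest.json` with the resolved
configuration and MD5 checksums of all artifacts.

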