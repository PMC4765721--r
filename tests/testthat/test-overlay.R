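# A small density image on disk to overlay on.
local_density_png <- function(dir, meta = plot_metadata(),
                              obs = data.frame(smoothed_depth = runif(100, 10, 90),
                                               smoothed_fraction = runif(100, 0, 0.5))) {
  path <- file.path(dir, "density.png")
  render_density(obs, meta, n_depth_bins = 50, n_fraction_bins = 25,
                 file = path)
  path
}

test_that("a pure-normal solution collapses all nodes to one depth column", {
  dir <- withr::local_tempdir()
  set.seed(1)
  img <- local_density_png(dir)
  res <- render_overlay(img, grid_solution(0, 20),
                        out_path = file.path(dir, "ov.png"))
  expect_true(all(res$nodes$predicted_depth == 40))
  expect_equal(length(unique(res$nodes$px)), 1L)
  expect_true(file.exists(file.path(dir, "ov.png")))
})

test_that("overlay rendering is deterministic and leaves the source intact", {
  dir <- withr::local_tempdir()
  set.seed(2)
  img <- local_density_png(dir)
  before <- readBin(img, "raw", file.size(img))
  r1 <- render_overlay(img, grid_solution(0.68, 15),
                       out_path = file.path(dir, "a.png"))
  r2 <- render_overlay(img, grid_solution(0.68, 15),
                       out_path = file.path(dir, "b.png"))
  expect_identical(readBin(file.path(dir, "a.png"), "raw",
                           file.size(file.path(dir, "a.png"))),
                   readBin(file.path(dir, "b.png"), "raw",
                           file.size(file.path(dir, "b.png"))))
  expect_identical(before, readBin(img, "raw", file.size(img)))
})

test_that("overlay nodes and a density of the same predictions coincide", {
  # render a density whose observations sit exactly at the predicted nodes;
  # the overlay's node pixels must match the density's occupied pixels
  # within one pixel (shared affine mapping)
  dir <- withr::local_tempdir()
  sol <- grid_solution(0.6, 12)
  grid <- build_grid(sol, max_total_copy = 4)
  meta <- plot_metadata()
  obs <- data.frame(smoothed_depth = grid$predicted_depth,
                    smoothed_fraction = grid$folded_fraction)
  path <- file.path(dir, "nodes.png")
  render_density(obs, meta, file = path)  # full-resolution binning
  res <- render_overlay(path, sol, max_total_copy = 4,
                        out_path = file.path(dir, "ov.png"))
  img <- render_density(obs, meta)
  occupied <- which(img$raster > 0, arr.ind = TRUE)
  occ_py <- meta$region_top + occupied[, 1] - 1L
  occ_px <- meta$region_left + occupied[, 2] - 1L
  for (i in seq_len(nrow(res$nodes))) {
    dist <- pmax(abs(occ_px - res$nodes$px[i]), abs(occ_py - res$nodes$py[i]))
    expect_lte(min(dist), 1L)
  }
})

test_that("folding moves nodes only near balance and at low depth", {
  dir <- withr::local_tempdir()
  set.seed(4)
  img <- local_density_png(dir, plot_metadata(depth_max = 200))
  sol <- grid_solution(0.9, 30)
  folded <- render_overlay(img, sol, style = overlay_style(show_fold = TRUE),
                           out_path = file.path(dir, "f.png"))
  raw <- render_overlay(img, sol, style = overlay_style(show_fold = FALSE),
                        out_path = file.path(dir, "r.png"))
  dy <- raw$nodes$py - folded$nodes$py
  expect_true(all(dy <= 0))  # folding only moves nodes downward in fraction
  # balanced low-depth nodes move the most
  moved <- folded$nodes[dy < 0, ]
  if (nrow(moved) > 0)
    expect_true(all(moved$predicted_fraction > 0.2))
})

test_that("a missing sidecar falls back to defaults with a warning", {
  dir <- withr::local_tempdir()
  set.seed(6)
  img <- local_density_png(dir)
  file.remove(sidecar_path <- sub("\\.png$", ".meta", img))
  expect_warning(
    render_overlay(img, grid_solution(0.5, 20),
                   out_path = file.path(dir, "ov.png")),
    "sidecar")
})

test_that("nodes outside the axis limits are skipped with a count", {
  dir <- withr::local_tempdir()
  set.seed(7)
  img <- local_density_png(dir, plot_metadata(depth_max = 50))
  expect_message(
    res <- render_overlay(img, grid_solution(1, 20),
                          out_path = file.path(dir, "ov.png")),
    "skipped")
  expect_gt(res$n_skipped, 0)
  expect_true(all(res$nodes$predicted_depth[res$nodes$in_range] <= 50))
})

test_that("the interactive session is drivable from a scripted connection", {
  dir <- withr::local_tempdir()
  set.seed(8)
  img <- local_density_png(dir)
  script <- textConnection(c("C 0.68", "D 15", "depth_range 0 120",
                             "export", "quit"))
  out <- capture.output(
    state <- interactive_session(img, input = script,
                                 preview_path = file.path(dir, "prev.png")))
  close(script)
  expect_equal(state$solution$cellularity, 0.68)
  expect_equal(state$solution$single_copy_depth, 15)
  expect_equal(state$metadata$depth_max, 120)
  expect_true(file.exists(file.path(dir, "prev.png")))
  expect_true(any(grepl("single_copy_depth\t15", out)))
  # out-of-range control values are rejected, state unchanged
  script2 <- textConnection(c("C 1.5", "quit"))
  out2 <- capture.output(
    state2 <- interactive_session(img, input = script2,
                                  preview_path = file.path(dir, "p2.png")))
  close(script2)
  expect_equal(state2$solution$cellularity, 0.5)
  expect_true(any(grepl("must be in", out2)))
})
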