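#' Plot geometry metadata for density images
#'
#' Records the axis limits and pixel geometry that make the density image
#' overlayable: depth on the x axis, minor-allele fraction (always
#' `[0, 0.5]`) on the y axis, and the pixel bounds of the data area
#' (`plot_region`) inside the image. The same metadata drives both the
#' rendering of the density and the placement of predicted grid nodes, so
#' the data-to-pixel mapping is shared and exact.
#'
#' @param depth_min,depth_max Depth axis limits in reads (defaults 0, 100).
#' @param image_width_px,image_height_px Image size in pixels (default
#'   800 x 800).
#' @param margin_px Margin around the plot region (default 60 px).
#' @return An object of class `"plot_metadata"`.
#' @export
plot_metadata <- function(depth_min = 0, depth_max = 100,
                          image_width_px = 800L, image_height_px = 800L,
                          margin_px = 60L) {
  m <- structure(list(
    depth_min = as.numeric(depth_min), depth_max = as.numeric(depth_max),
    fraction_min = 0, fraction_max = 0.5,
    image_width_px = as.integer(image_width_px),
    image_height_px = as.integer(image_height_px),
    region_left = as.integer(margin_px) + 1L,
    region_right = as.integer(image_width_px) - as.integer(margin_px),
    region_top = as.integer(margin_px) + 1L,
    region_bottom = as.integer(image_height_px) - as.integer(margin_px)),
    class = "plot_metadata")
  validate_plot_metadata(m)
}

validate_plot_metadata <- function(m) {
  if (m$depth_min >= m$depth_max)
    stop("'depth_min' must be below 'depth_max'", call. = FALSE)
  if (m$region_left <= 1L || m$region_top <= 1L ||
      m$region_right >= m$image_width_px ||
      m$region_bottom >= m$image_height_px ||
      m$region_left >= m$region_right || m$region_top >= m$region_bottom)
    stop("plot region must lie strictly inside the image", call. = FALSE)
  m
}

#' @export
print.plot_metadata <- function(x, ...) {
  cat(sprintf(
    "Plot metadata: depth [%g, %g], fraction [%g, %g]\n  image %d x %d px, plot region x [%d, %d], y [%d, %d]\n",
    x$depth_min, x$depth_max, x$fraction_min, x$fraction_max,
    x$image_width_px, x$image_height_px,
    x$region_left, x$region_right, x$region_top, x$region_bottom))
  invisible(x)
}

#' Map data coordinates to image pixels, and back
#'
#' The mapping is affine: depth runs left to right across the plot region
#' and fraction runs bottom to top (pixel row numbers increase downward).
#' Returned pixel coordinates are continuous; round them to draw. The
#' inverse `pixel_to_data` round-trips to within one pixel's worth of data
#' units.
#'
#' @param depth,fraction Data coordinates.
#' @param px,py Pixel coordinates (x = column, y = row, 1-based).
#' @param metadata A [plot_metadata()].
#' @return A data.frame with columns `px`, `py` (or `depth`, `fraction`).
#' @export
data_to_pixel <- function(depth, fraction, metadata) {
  sx <- (metadata$region_right - metadata$region_left) /
    (metadata$depth_max - metadata$depth_min)
  sy <- (metadata$region_bottom - metadata$region_top) /
    (metadata$fraction_max - metadata$fraction_min)
  data.frame(
    px = metadata$region_left + (depth - metadata$depth_min) * sx,
    py = metadata$region_bottom - (fraction - metadata$fraction_min) * sy)
}

#' @rdname data_to_pixel
#' @export
pixel_to_data <- function(px, py, metadata) {
  sx <- (metadata$region_right - metadata$region_left) /
    (metadata$depth_max - metadata$depth_min)
  sy <- (metadata$region_bottom - metadata$region_top) /
    (metadata$fraction_max - metadata$fraction_min)
  data.frame(
    depth = metadata$depth_min + (px - metadata$region_left) / sx,
    fraction = metadata$fraction_min + (metadata$region_bottom - py) / sy)
}

#' Write / read the sidecar metadata file for a density image
#'
#' Plain `key=value` text recording the geometry of a rendered PNG, written
#' next to the image so that an overlay can reconstruct the exact
#' data-to-pixel mapping. Images supplied without a sidecar are assigned
#' the default metadata with a warning.
#'
#' @param metadata A [plot_metadata()].
#' @param path Path of the `.meta` file.
#' @return `write_plot_metadata` returns `path` invisibly;
#'   `read_plot_metadata` returns a [plot_metadata()]-classed object.
#' @export
write_plot_metadata <- function(metadata, path) {
  keys <- c("depth_min", "depth_max", "fraction_min", "fraction_max",
            "image_width_px", "image_height_px", "region_left",
            "region_right", "region_top", "region_bottom")
  writeLines(paste0(keys, "=", vapply(keys, function(k)
    format(metadata[[k]], scientific = FALSE), "")), path)
  invisible(path)
}

#' @rdname write_plot_metadata
#' @export
read_plot_metadata <- function(path) {
  lines <- readLines(path)
  lines <- lines[grepl("=", lines, fixed = TRUE)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- stats::setNames(as.numeric(vapply(kv, `[`, "", 2L)),
                          trimws(vapply(kv, `[`, "", 1L)))
  m <- structure(as.list(vals[c(
    "depth_min", "depth_max", "fraction_min", "fraction_max",
    "image_width_px", "image_height_px", "region_left", "region_right",
    "region_top", "region_bottom")]), class = "plot_metadata")
  int_keys <- c("image_width_px", "image_height_px", "region_left",
                "region_right", "region_top", "region_bottom")
  m[int_keys] <- lapply(m[int_keys], as.integer)
  validate_plot_metadata(m)
}

# Sidecar path convention: sample.png -> sample.meta
sidecar_path <- function(png_path) sub("\\.png$", ".meta", png_path)

#' Render the 2D density image of depth versus minor-allele fraction
#'
#' Bins (smoothed) observations into a 2D histogram over the axis limits,
#' optionally applies a Gaussian blur, and rasterises the result into the
#' plot region. Observations outside the axis limits are dropped with a
#' message reporting the count; if all points fall outside, rendering
#' fails naming the limits. When `file` is given, a grayscale PNG
#' (dark = dense) and its `.meta` sidecar are written.
#'
#' @param obs Observations: either smoothed (`smoothed_depth`,
#'   `smoothed_fraction`) or raw (`depth`, `minor_fraction`) columns.
#' @param metadata A [plot_metadata()] (default [plot_metadata()]).
#' @param n_depth_bins,n_fraction_bins Histogram resolution; defaults to
#'   the plot region's pixel dimensions.
#' @param kernel_smooth_sigma Gaussian blur standard deviation in bins
#'   (default 0 = no blur).
#' @param file Optional output PNG path.
#' @return An object of class `"density_image"`: a list with `counts` (the
#'   histogram matrix, fraction bins x depth bins, before rasterisation),
#'   `raster` (plot-region-sized matrix, image orientation), `metadata`,
#'   `depth_breaks`, `fraction_breaks`, `n_in_range`, `n_clipped`.
#' @export
render_density <- function(obs, metadata = plot_metadata(),
                           n_depth_bins = NULL, n_fraction_bins = NULL,
                           kernel_smooth_sigma = 0, file = NULL) {
  d <- if ("smoothed_depth" %in% names(obs)) obs$smoothed_depth else obs$depth
  f <- if ("smoothed_fraction" %in% names(obs)) obs$smoothed_fraction
       else obs$minor_fraction
  if (is.null(d) || is.null(f) || length(d) == 0L)
    stop("no observations to render", call. = FALSE)
  region_w <- metadata$region_right - metadata$region_left + 1L
  region_h <- metadata$region_bottom - metadata$region_top + 1L
  if (is.null(n_depth_bins)) n_depth_bins <- region_w
  if (is.null(n_fraction_bins)) n_fraction_bins <- region_h

  in_range <- d >= metadata$depth_min & d <= metadata$depth_max &
    f >= metadata$fraction_min & f <= metadata$fraction_max
  n_clipped <- sum(!in_range)
  if (!any(in_range))
    stop("all observations fall outside the axis limits (depth [",
         metadata$depth_min, ", ", metadata$depth_max, "], fraction [",
         metadata$fraction_min, ", ", metadata$fraction_max, "])",
         call. = FALSE)
  if (n_clipped > 0L)
    message(n_clipped, " observation(s) outside the axis limits dropped")
  d <- d[in_range]; f <- f[in_range]

  ix <- bin_index(d, metadata$depth_min, metadata$depth_max, n_depth_bins)
  iy <- bin_index(f, metadata$fraction_min, metadata$fraction_max,
                  n_fraction_bins)
  counts <- matrix(0, nrow = n_fraction_bins, ncol = n_depth_bins)
  tab <- table(factor(iy, levels = seq_len(n_fraction_bins)),
               factor(ix, levels = seq_len(n_depth_bins)))
  counts[] <- as.numeric(tab)

  smoothed <- if (kernel_smooth_sigma > 0)
    gaussian_blur(counts, kernel_smooth_sigma) else counts

  # rasterise to plot-region pixels (nearest neighbour); row 1 = top row
  col_of <- ceiling(seq_len(region_w) / region_w * n_depth_bins)
  row_of <- ceiling(seq_len(region_h) / region_h * n_fraction_bins)
  raster <- smoothed[row_of, col_of, drop = FALSE][region_h:1, , drop = FALSE]

  img <- structure(list(
    counts = counts, smoothed_counts = smoothed, raster = raster,
    metadata = metadata,
    depth_breaks = seq(metadata$depth_min, metadata$depth_max,
                       length.out = n_depth_bins + 1L),
    fraction_breaks = seq(metadata$fraction_min, metadata$fraction_max,
                          length.out = n_fraction_bins + 1L),
    n_in_range = length(d), n_clipped = n_clipped),
    class = "density_image")
  if (!is.null(file)) write_density_png(img, file)
  img
}

# 1-based bin index over [lo, hi]; the upper limit falls in the last bin.
bin_index <- function(x, lo, hi, n) {
  i <- floor((x - lo) / (hi - lo) * n) + 1L
  pmin.int(pmax.int(i, 1L), n)
}

# Separable Gaussian convolution with zero padding at edges.
gaussian_blur <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  conv_rows <- function(x) {
    out <- matrix(0, nrow(x), ncol(x))
    for (j in -r:r) {
      src <- seq_len(ncol(x)) + j
      ok <- src >= 1L & src <= ncol(x)
      out[, ok] <- out[, ok] + k[j + r + 1L] * x[, src[ok], drop = FALSE]
    }
    out
  }
  t(conv_rows(t(conv_rows(m))))
}

#' @export
print.density_image <- function(x, ...) {
  cat(sprintf(
    "Density image: %d observations binned %d x %d (fraction x depth), %d clipped\n",
    x$n_in_range, nrow(x$counts), ncol(x$counts), x$n_clipped))
  print(x$metadata)
  invisible(x)
}

# Write the density as a grayscale PNG with a border around the plot
# region, plus the .meta sidecar.
write_density_png <- function(img, file) {
  m <- img$metadata
  arr <- array(1, dim = c(m$image_height_px, m$image_width_px, 3L))
  mx <- max(img$raster)
  shade <- if (mx > 0) 1 - img$raster / mx else
    matrix(1, nrow(img$raster), ncol(img$raster))
  rows <- m$region_top:m$region_bottom
  cols <- m$region_left:m$region_right
  for (ch in 1:3) arr[rows, cols, ch] <- shade
  # 1-px border just outside the region
  arr[c(m$region_top - 1L, m$region_bottom + 1L),
      (m$region_left - 1L):(m$region_right + 1L), ] <- 0
  arr[(m$region_top - 1L):(m$region_bottom + 1L),
      c(m$region_left - 1L, m$region_right + 1L), ] <- 0
  png::writePNG(arr, file)
  write_plot_metadata(m, sidecar_path(file))
  invisible(file)
}

#' Find density modes by connected components
#'
#' Labels the connected components (4-connectivity) of histogram bins
#' whose count exceeds a threshold, and reports each component's peak in
#' data coordinates. Used to count distinct copy-number states visible in
#' a density image and to check which of them a candidate solution's grid
#' covers.
#'
#' @param img A [render_density()] result.
#' @param threshold Absolute bin-count threshold; default 5% of the
#'   maximum bin count.
#' @return A data.frame with one row per mode: `depth`, `fraction` (peak
#'   bin centre), `mass` (total count in the component), `n_bins`.
#' @export
find_modes <- function(img, threshold = NULL) {
  stopifnot(inherits(img, "density_image"))
  counts <- img$smoothed_counts
  if (is.null(threshold)) threshold <- 0.05 * max(counts)
  lab <- label_components(counts > threshold)
  n_modes <- max(lab)
  if (n_modes == 0L)
    return(data.frame(depth = numeric(0), fraction = numeric(0),
                      mass = numeric(0), n_bins = integer(0)))
  dc <- (img$depth_breaks[-1] + img$depth_breaks[-length(img$depth_breaks)]) / 2
  fc <- (img$fraction_breaks[-1] +
         img$fraction_breaks[-length(img$fraction_breaks)]) / 2
  out <- lapply(seq_len(n_modes), function(l) {
    idx <- which(lab == l, arr.ind = TRUE)
    vals <- counts[lab == l]
    peak <- idx[which.max(vals), ]
    data.frame(depth = dc[peak[2L]], fraction = fc[peak[1L]],
               mass = sum(vals), n_bins = nrow(idx))
  })
  out <- do.call(rbind, out)
  out[order(-out$mass), , drop = FALSE]
}

# 4-connected component labelling of a logical matrix (iterative BFS).
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  current <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    current <- current + 1L
    queue <- start
    lab[start] <- current
    while (length(queue) > 0L) {
      cell <- queue[[1L]]; queue <- queue[-1L]
      r <- (cell - 1L) %% nr + 1L
      cl <- (cell - 1L) %/% nr + 1L
      for (nb in list(c(r - 1L, cl), c(r + 1L, cl), c(r, cl - 1L), c(r, cl + 1L))) {
        if (nb[1L] >= 1L && nb[1L] <= nr && nb[2L] >= 1L && nb[2L] <= nc) {
          idx <- (nb[2L] - 1L) * nr + nb[1L]
          if (mask[idx] && lab[idx] == 0L) {
            lab[idx] <- current
            queue <- c(queue, idx)
          }
        }
      }
    }
  }
  lab
}
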