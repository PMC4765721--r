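#' Styling for grid-node overlays
#'
#' @param marker_size Cross-marker arm length in pixels (default 5).
#' @param colour Marker colour (any R colour; default `"red"`).
#' @param label Node label format reported in the returned node table:
#'   `"total"` (total copy number) or `"pair"` (`"(n1,n2)"`).
#' @param show_fold If `TRUE` (default) nodes are placed at the folded
#'   expected fraction; if `FALSE` at the raw predicted fraction.
#' @return An object of class `"overlay_style"`.
#' @export
overlay_style <- function(marker_size = 5L, colour = "red",
                          label = c("total", "pair"), show_fold = TRUE) {
  if (marker_size <= 0) stop("'marker_size' must be positive", call. = FALSE)
  structure(list(marker_size = as.integer(marker_size), colour = colour,
                 label = match.arg(label), show_fold = isTRUE(show_fold)),
            class = "overlay_style")
}

# Load a PNG and its geometry; a missing sidecar gets default margins for
# the image's actual pixel dimensions, with a warning.
load_image_with_metadata <- function(image_path) {
  if (!file.exists(image_path))
    stop("image not found: ", image_path, call. = FALSE)
  arr <- png::readPNG(image_path)
  if (length(dim(arr)) == 2L) arr <- array(rep(arr, 3L), dim = c(dim(arr), 3L))
  arr <- arr[, , 1:3, drop = FALSE]
  meta_file <- sidecar_path(image_path)
  if (file.exists(meta_file)) {
    meta <- read_plot_metadata(meta_file)
  } else {
    warning("no sidecar metadata found for '", image_path,
            "'; assuming default axis limits and a 60-px margin",
            call. = FALSE)
    meta <- plot_metadata(image_width_px = dim(arr)[2L],
                          image_height_px = dim(arr)[1L])
  }
  if (meta$image_width_px != dim(arr)[2L] ||
      meta$image_height_px != dim(arr)[1L])
    stop("sidecar metadata image size (", meta$image_width_px, " x ",
         meta$image_height_px, ") does not match the PNG (", dim(arr)[2L],
         " x ", dim(arr)[1L], ")", call. = FALSE)
  list(arr = arr, metadata = meta)
}

#' Superimpose a solution's predicted grid on a density image
#'
#' Draws the copy-number lattice predicted by a candidate (cellularity,
#' single-copy depth) solution onto a rendered density image, using the
#' image's sidecar metadata for the exact data-to-pixel mapping. Nodes
#' whose predicted depth or fraction falls outside the axis limits are
#' skipped with a message. The source image is never modified; the
#' composition is written to `out_path`.
#'
#' @param image_path Path to the density PNG (with `.meta` sidecar).
#' @param solution A [grid_solution()].
#' @param max_total_copy Largest total copy number to draw (default 8).
#' @param style An [overlay_style()].
#' @param out_path Output PNG path.
#' @param metadata Optional [plot_metadata()] overriding the sidecar (used
#'   when axis limits are being edited without touching the files on
#'   disk).
#' @return Invisibly, a list with `nodes` (the grid table with pixel
#'   coordinates, labels and an `in_range` flag), `n_skipped`, `metadata`
#'   and `out_path`.
#' @export
render_overlay <- function(image_path, solution, max_total_copy = 8L,
                           style = overlay_style(),
                           out_path = sub("\\.png$", "-overlay.png",
                                          image_path),
                           metadata = NULL) {
  stopifnot(inherits(solution, "grid_solution"),
            inherits(style, "overlay_style"))
  im <- load_image_with_metadata(image_path)
  meta <- if (is.null(metadata)) im$metadata else validate_plot_metadata(metadata)
  grid <- build_grid(solution, max_total_copy, fold = style$show_fold)
  y <- grid$folded_fraction
  pix <- data_to_pixel(grid$predicted_depth, y, meta)
  grid$px <- round(pix$px)
  grid$py <- round(pix$py)
  grid$label <- if (style$label == "total") as.character(grid$total_copy)
                else sprintf("(%d,%d)", grid$n1, grid$n2)
  grid$in_range <- grid$predicted_depth >= meta$depth_min &
    grid$predicted_depth <= meta$depth_max &
    y >= meta$fraction_min & y <= meta$fraction_max
  n_skipped <- sum(!grid$in_range)
  if (n_skipped > 0L)
    message(n_skipped, " node(s) outside the axis limits skipped")

  arr <- im$arr
  rgb <- grDevices::col2rgb(style$colour)[, 1L] / 255
  s <- style$marker_size
  for (i in which(grid$in_range)) {
    arr <- draw_cross(arr, grid$py[i], grid$px[i], s, rgb)
  }
  png::writePNG(arr, out_path)
  if (file.exists(sidecar_path(image_path)))
    file.copy(sidecar_path(image_path), sidecar_path(out_path),
              overwrite = TRUE)
  invisible(list(nodes = grid, n_skipped = n_skipped, metadata = meta,
                 out_path = out_path))
}

# Paint a 1-px cross of arm length s centred at (row, col), clipped to the
# image.
draw_cross <- function(arr, row, col, s, rgb) {
  h <- dim(arr)[1L]; w <- dim(arr)[2L]
  rows <- (row - s):(row + s); rows <- rows[rows >= 1L & rows <= h]
  cols <- (col - s):(col + s); cols <- cols[cols >= 1L & cols <= w]
  if (col >= 1L && col <= w)
    for (ch in 1:3) arr[rows, col, ch] <- rgb[ch]
  if (row >= 1L && row <= h)
    for (ch in 1:3) arr[row, cols, ch] <- rgb[ch]
  arr
}

#' Interactively explore (cellularity, depth) solutions over an image
#'
#' A text-command session over [render_overlay()]: two continuous
#' controls — the cellularity `C` in `[0, 1]` and the single-copy depth
#' `D` in `(0, depth_max / 2]` — plus metadata editing (depth axis range),
#' with the overlay re-rendered to a preview file after every change. All
#' computation lives in the library functions, so the session is a thin,
#' scriptable view: any connection can drive it.
#'
#' Commands (one per line): `C <value>`, `D <value>`,
#' `depth_range <min> <max>`, `fold on|off`, `export`, `quit`.
#'
#' @param image_path Path to the density PNG.
#' @param input Connection to read commands from (default `stdin()`).
#' @param preview_path Path the preview overlay is re-rendered to.
#' @param max_total_copy Largest total copy number to draw.
#' @param style An [overlay_style()].
#' @return Invisibly, the exported state: a list with the current
#'   [grid_solution()], the metadata in force, and `preview_path`.
#' @export
interactive_session <- function(image_path, input = stdin(),
                                preview_path = file.path(
                                  tempdir(), "overlay-preview.png"),
                                max_total_copy = 8L,
                                style = overlay_style()) {
  im <- load_image_with_metadata(image_path)
  meta <- im$metadata
  C <- 0.5
  D <- meta$depth_max / 4
  rerender <- function() {
    res <- render_overlay(image_path, grid_solution(C, D), max_total_copy,
                          style, out_path = preview_path, metadata = meta)
    cat(sprintf("C = %.3f, D = %.2f -> %s\n", C, D, preview_path))
    res
  }
  rerender()
  repeat {
    line <- readLines(input, n = 1L)
    if (length(line) == 0L) break
    tok <- strsplit(trimws(line), "\\s+")[[1L]]
    if (length(tok) == 0L || tok[1L] == "") next
    cmd <- tok[1L]
    if (cmd == "quit") break
    if (cmd == "export") {
      cat(sprintf("cellularity\t%g\nsingle_copy_depth\t%g\n", C, D))
      next
    }
    if (cmd == "C" && length(tok) >= 2L) {
      val <- as.numeric(tok[2L])
      if (is.na(val) || val < 0 || val > 1) {
        cat("C must be in [0, 1]\n"); next
      }
      C <- val
    } else if (cmd == "D" && length(tok) >= 2L) {
      val <- as.numeric(tok[2L])
      if (is.na(val) || val <= 0 || val > meta$depth_max / 2) {
        cat(sprintf("D must be in (0, %g]\n", meta$depth_max / 2)); next
      }
      D <- val
    } else if (cmd == "depth_range" && length(tok) >= 3L) {
      lo <- as.numeric(tok[2L]); hi <- as.numeric(tok[3L])
      if (is.na(lo) || is.na(hi) || lo >= hi) {
        cat("usage: depth_range <min> <max>\n"); next
      }
      meta$depth_min <- lo; meta$depth_max <- hi
    } else if (cmd == "fold" && length(tok) >= 2L) {
      style$show_fold <- identical(tok[2L], "on")
    } else {
      cat("commands: C <v> | D <v> | depth_range <min> <max> | fold on|off | export | quit\n")
      next
    }
    rerender()
  }
  invisible(list(solution = grid_solution(C, D), metadata = meta,
                 preview_path = preview_path))
}
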