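# Pull (depth, fraction) columns out of a smoothed or raw observation
# table.
obs_coords <- function(obs) {
  d <- if ("smoothed_depth" %in% names(obs)) obs$smoothed_depth else obs$depth
  f <- if ("smoothed_fraction" %in% names(obs)) obs$smoothed_fraction
       else obs$minor_fraction
  if (is.null(d) || is.null(f) || length(d) == 0L)
    stop("no observations", call. = FALSE)
  list(d = as.numeric(d), f = as.numeric(f))
}

# Distance from each observation to its nearest grid node, in normalised
# coordinates: sqrt((ddepth/depth_scale)^2 + (dfraction/fraction_scale)^2).
nearest_node_distance <- function(d, f, grid, depth_scale, fraction_scale,
                                  fold = TRUE) {
  y <- if (fold) grid$folded_fraction else grid$predicted_fraction
  m <- nrow(grid)
  dmin <- rep(Inf, length(d))
  which_node <- rep(NA_integer_, length(d))
  for (j in seq_len(m)) {
    dj <- sqrt(((d - grid$predicted_depth[j]) / depth_scale)^2 +
               ((f - y[j]) / fraction_scale)^2)
    better <- dj < dmin
    dmin[better] <- dj[better]
    which_node[better] <- j
  }
  list(distance = dmin, node = which_node)
}

#' Score a (cellularity, depth) solution against observations
#'
#' Measures how well a candidate solution's predicted copy-number lattice
#' explains the observed (smoothed) depth/minor-fraction cloud. Each
#' observation's distance to its nearest grid node is computed in
#' normalised coordinates — depth differences divided by `depth_scale`
#' (default `D / 2`, half a copy's worth of depth) and fraction
#' differences by `fraction_scale` (default 0.05) — so one unit of
#' distance means "one half-copy of depth or five points of allele
#' fraction away from the lattice".
#'
#' `mean_distance` is a trimmed mean of these distances (robust to a small
#' share of off-lattice, e.g. sub-clonal, mass); `fraction_explained`
#' reports separately the share of observations within distance 1 of some
#' node, so off-lattice mass is surfaced rather than averaged away.
#'
#' @param obs Observations (smoothed preferred; raw columns accepted).
#' @param solution A [grid_solution()].
#' @param max_total_copy Largest total copy number in the lattice.
#' @param depth_scale Depth normalisation; default `single_copy_depth / 2`.
#' @param fraction_scale Fraction normalisation (default 0.05).
#' @param trim Trim fraction for the mean distance (default 0.05).
#' @param fold Place nodes at folded expected fractions (default `TRUE`).
#' @return An object of class `"fit_score"`: a list with `solution`,
#'   `mean_distance`, `fraction_explained`, `n`.
#' @export
fit_score <- function(obs, solution, max_total_copy = 8L,
                      depth_scale = NULL, fraction_scale = 0.05,
                      trim = 0.05, fold = TRUE) {
  stopifnot(inherits(solution, "grid_solution"))
  if (is.null(depth_scale)) depth_scale <- solution$single_copy_depth / 2
  if (depth_scale <= 0 || fraction_scale <= 0)
    stop("scales must be positive", call. = FALSE)
  co <- obs_coords(obs)
  grid <- suppressMessages(build_grid(solution, max_total_copy, fold = fold))
  nn <- nearest_node_distance(co$d, co$f, grid, depth_scale, fraction_scale,
                              fold = fold)
  structure(list(solution = solution,
                 mean_distance = mean(nn$distance, trim = trim),
                 fraction_explained = mean(nn$distance <= 1),
                 n = length(co$d),
                 depth_scale = depth_scale,
                 fraction_scale = fraction_scale),
            class = "fit_score")
}

#' @export
print.fit_score <- function(x, ...) {
  cat(sprintf(
    "Fit of C = %.3f, D = %.3f over %d observations:\n  trimmed mean distance %.4f, fraction explained %.3f\n",
    x$solution$cellularity, x$solution$single_copy_depth, x$n,
    x$mean_distance, x$fraction_explained))
  invisible(x)
}

#' Exhaustive grid search over candidate solutions
#'
#' Evaluates [fit_score()] for every combination of the supplied
#' cellularity and single-copy-depth values and returns all scores ranked
#' by mean distance (ties broken deterministically by lower cellularity,
#' then lower depth). The full ranked table is returned, never just the
#' winner: distinct solutions — notably genome-doubled pairs at halved or
#' doubled `D` — can explain the same modes, and adjudicating between
#' near-ties is the user's task, informed by tumour biology.
#'
#' @inheritParams fit_score
#' @param C_grid,D_grid Numeric vectors of candidate cellularities and
#'   single-copy depths.
#' @param max_obs Observations are thinned deterministically (evenly
#'   spaced) to at most this many before scoring (default 1000).
#' @return A data.frame of class `"grid_search"` with columns
#'   `cellularity`, `single_copy_depth`, `mean_distance`,
#'   `fraction_explained`, ranked best-first.
#' @export
grid_search <- function(obs, C_grid, D_grid, max_total_copy = 8L,
                        depth_scale = NULL, fraction_scale = 0.05,
                        trim = 0.05, fold = TRUE, max_obs = 1000L) {
  if (length(C_grid) == 0L || length(D_grid) == 0L)
    stop("'C_grid' and 'D_grid' must be nonempty", call. = FALSE)
  co <- obs_coords(obs)
  if (length(co$d) > max_obs) {
    idx <- unique(round(seq(1L, length(co$d), length.out = max_obs)))
    co$d <- co$d[idx]; co$f <- co$f[idx]
  }
  thin <- data.frame(smoothed_depth = co$d, smoothed_fraction = co$f)
  combos <- expand.grid(D = D_grid, C = C_grid)
  scores <- lapply(seq_len(nrow(combos)), function(i) {
    s <- fit_score(thin, grid_solution(combos$C[i], combos$D[i]),
                   max_total_copy, depth_scale, fraction_scale, trim, fold)
    c(s$mean_distance, s$fraction_explained)
  })
  scores <- do.call(rbind, scores)
  out <- data.frame(cellularity = combos$C, single_copy_depth = combos$D,
                    mean_distance = scores[, 1L],
                    fraction_explained = scores[, 2L])
  out <- out[order(out$mean_distance, out$cellularity,
                   out$single_copy_depth), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("grid_search", "data.frame")
  out
}

#' Fit the copy-number grid model to locus observations
#'
#' The package's main fitting interface: smooths the observations (unless
#' already smoothed), grid-searches the (cellularity, single-copy depth)
#' plane, and returns a classed fit object with the usual accessor
#' methods. The "model" is the clonal copy-number lattice: each state
#' `(n1, n2)` predicts a depth `D * (2(1 - C) + (n1 + n2) C)` and a folded
#' expected minor-allele fraction; the fit measures how close the observed
#' density lies to the nearest lattice node.
#'
#' The returned object keeps the full ranked solution table. Because of
#' genuine identifiability aliasing (genome-doubling moves every even-copy
#' state onto another lattice), inspect `summary()` — which flags
#' near-tied solutions at roughly halved/doubled depth — rather than
#' trusting `coef()` blindly.
#'
#' @inheritParams grid_search
#' @param C_grid,D_grid Candidate grids (defaults: C from 0.3 to 0.95 by
#'   0.01; D from 5 to 40 by 0.5).
#' @param smooth_window Running-smooth window applied when `obs` is raw
#'   (default 51); `statistic` as in [running_smooth()].
#' @param statistic Smoothing statistic. The fit defaults to `"mean"`,
#'   unlike [running_smooth()]: grid nodes predict the *mean* of the
#'   folded fraction distribution, which is left-skewed near balance, so
#'   median-smoothed fractions sit systematically above the folded nodes
#'   and bias the fitted cellularity slightly downward at low purity.
#' @return An object of class `"baf_grid_fit"`.
#' @seealso [fit_score()], [grid_search()], [render_overlay()]
#' @examples
#' prof <- segment_profile(n1 = c(1, 2, 2), n2 = c(1, 0, 2),
#'                         n_loci = c(60, 60, 60))
#' truth <- sim_truth(prof, grid_solution(0.7, 15), seed = 1)
#' obs <- simulate_observations(truth)
#' fit <- fit_baf_grid(obs, C_grid = seq(0.5, 0.9, 0.05),
#'                     D_grid = seq(10, 20, 1))
#' coef(fit)
#' @export
fit_baf_grid <- function(obs, C_grid = seq(0.3, 0.95, by = 0.01),
                         D_grid = seq(5, 40, by = 0.5),
                         smooth_window = 51L,
                         statistic = c("mean", "median"),
                         max_total_copy = 8L, depth_scale = NULL,
                         fraction_scale = 0.05, trim = 0.05, fold = TRUE,
                         max_obs = 1000L) {
  statistic <- match.arg(statistic)
  cl <- match.call()
  smoothed <- if ("smoothed_depth" %in% names(obs)) obs
              else running_smooth(obs, smooth_window, statistic)
  ranked <- grid_search(smoothed, C_grid, D_grid, max_total_copy,
                        depth_scale, fraction_scale, trim, fold, max_obs)
  best <- grid_solution(ranked$cellularity[1L], ranked$single_copy_depth[1L])
  structure(list(ranked = ranked, solution = best, observations = smoothed,
                 C_grid = sort(unique(C_grid)), D_grid = sort(unique(D_grid)),
                 max_total_copy = max_total_copy,
                 depth_scale = depth_scale, fraction_scale = fraction_scale,
                 trim = trim, fold = fold, call = cl),
            class = "baf_grid_fit")
}

#' @export
print.baf_grid_fit <- function(x, ...) {
  cat("Copy-number grid fit\n")
  cat("Call: "); print(x$call)
  cat(sprintf("Best solution of %d evaluated: C = %.3f, D = %.3f\n",
              nrow(x$ranked), x$solution$cellularity,
              x$solution$single_copy_depth))
  cat(sprintf("  trimmed mean distance %.4f, fraction explained %.3f (n = %d)\n",
              x$ranked$mean_distance[1L], x$ranked$fraction_explained[1L],
              nrow(x$observations)))
  invisible(x)
}

#' @export
coef.baf_grid_fit <- function(object, ...) {
  c(cellularity = object$solution$cellularity,
    single_copy_depth = object$solution$single_copy_depth)
}

#' Summarise a grid fit, flagging aliased solutions
#'
#' Reports the top-ranked solutions and flags near-ties whose single-copy
#' depth is close to half or double the best solution's — the
#' genome-doubling aliasing class that makes this estimation problem only
#' partially identifiable.
#'
#' @param object A [fit_baf_grid()] result.
#' @param n_top Number of leading solutions to show (default 10).
#' @param tie_tolerance Relative mean-distance margin defining a near-tie
#'   (default 0.1).
#' @param ... Unused.
#' @export
summary.baf_grid_fit <- function(object, n_top = 10L, tie_tolerance = 0.1,
                                 ...) {
  r <- object$ranked
  best <- r[1L, ]
  ties <- r[r$mean_distance <= best$mean_distance * (1 + tie_tolerance), ,
            drop = FALSE]
  ratio <- ties$single_copy_depth / best$single_copy_depth
  aliased <- ties[abs(ratio - 2) < 0.15 | abs(ratio - 0.5) < 0.04, ,
                  drop = FALSE]
  structure(list(top = utils::head(r, n_top), best = best,
                 n_tied = nrow(ties), aliased = aliased,
                 tie_tolerance = tie_tolerance),
            class = "summary.baf_grid_fit")
}

#' @export
print.summary.baf_grid_fit <- function(x, ...) {
  cat("Top solutions (ranked by trimmed mean distance):\n")
  print(format(x$top, digits = 4), row.names = FALSE)
  cat(sprintf("\n%d solution(s) within %.0f%% of the best score.\n",
              x$n_tied, 100 * x$tie_tolerance))
  if (nrow(x$aliased) > 0L) {
    cat("Near-tied solutions at ~half/double the best depth (genome-doubling aliasing):\n")
    print(format(x$aliased, digits = 4), row.names = FALSE)
    cat("The data alone cannot adjudicate these; use knowledge of the tumour's likely ploidy.\n")
  }
  invisible(x)
}

#' Predicted lattice of a fitted solution
#'
#' @param object A [fit_baf_grid()] result.
#' @param solution Optional [grid_solution()] to predict for instead of
#'   the fitted one.
#' @param ... Unused.
#' @return The [build_grid()] node table.
#' @export
predict.baf_grid_fit <- function(object, solution = NULL, ...) {
  if (is.null(solution)) solution <- object$solution
  suppressMessages(build_grid(solution, object$max_total_copy,
                              fold = object$fold))
}

#' @export
residuals.baf_grid_fit <- function(object, ...) {
  co <- obs_coords(object$observations)
  grid <- predict(object)
  ds <- if (is.null(object$depth_scale))
    object$solution$single_copy_depth / 2 else object$depth_scale
  nearest_node_distance(co$d, co$f, grid, ds, object$fraction_scale,
                        fold = object$fold)$distance
}

#' Plot a grid fit: observations with the fitted lattice superimposed
#'
#' @param x A [fit_baf_grid()] result.
#' @param solution Optional alternative solution to overlay.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.baf_grid_fit <- function(x, solution = NULL, ...) {
  co <- obs_coords(x$observations)
  grid <- predict(x, solution)
  graphics::plot(co$d, co$f, pch = 16, cex = 0.4,
                 col = grDevices::grey(0.4, alpha = 0.5),
                 xlab = "depth (reads)", ylab = "minor-allele fraction",
                 ylim = c(0, 0.5), ...)
  y <- if (x$fold) grid$folded_fraction else grid$predicted_fraction
  graphics::points(grid$predicted_depth, y, pch = 3, col = "red", cex = 1.2)
  graphics::text(grid$predicted_depth, y,
                 labels = sprintf("(%d,%d)", grid$n1, grid$n2),
                 pos = 3, cex = 0.6, col = "red")
  invisible(x)
}

#' Simulate new observations from a fitted solution
#'
#' Assigns each smoothed observation to its nearest lattice node and draws
#' fresh per-locus depths (Poisson around the node's predicted depth) and
#' allele counts (binomial around the node's phased fraction), folded at
#' 0.5 — a parametric-bootstrap-style replicate of the fitted clonal
#' model.
#'
#' @param object A [fit_baf_grid()] result.
#' @param nsim Number of replicates (default 1).
#' @param seed Optional seed.
#' @param ... Unused.
#' @return A data.frame for `nsim = 1`, else a list of data.frames.
#' @export
simulate.baf_grid_fit <- function(object, nsim = 1, seed = NULL, ...) {
  co <- obs_coords(object$observations)
  grid <- predict(object)
  ds <- if (is.null(object$depth_scale))
    object$solution$single_copy_depth / 2 else object$depth_scale
  nn <- nearest_node_distance(co$d, co$f, grid, ds, object$fraction_scale,
                              fold = object$fold)
  states <- grid[nn$node, c("n1", "n2"), drop = FALSE]
  prof <- data.frame(chrom = object$observations$chrom,
                     pos = object$observations$pos,
                     n1 = states$n1, n2 = states$n2)
  one <- function(s) {
    truth <- sim_truth(
      segment_profile(chrom = prof$chrom, start = prof$pos, end = prof$pos,
                      n1 = prof$n1, n2 = prof$n2,
                      n_loci = rep(1L, nrow(prof))),
      object$solution, seed = s)
    simulate_observations(truth)
  }
  base_seed <- if (is.null(seed)) sample.int(.Machine$integer.max, 1L)
               else as.integer(seed)
  sims <- lapply(seq_len(nsim), function(i) one(base_seed + i - 1L))
  if (nsim == 1) sims[[1L]] else sims
}
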