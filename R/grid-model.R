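#' Candidate cellularity / single-copy-depth solution
#'
#' A grid solution is the pair of parameters that positions the clonal
#' copy-number lattice on a (depth, minor-allele fraction) plot: the
#' cellularity `C` (fraction of cells in the sample that are tumour cells)
#' and the single-copy depth `D` (sequencing depth contributed by one
#' chromosomal copy present in every cell; half the depth of a diploid
#' region in a pure sample).
#'
#' @param cellularity Tumour cell fraction, in `[0, 1]`.
#' @param single_copy_depth Depth of a single copy, in reads; must be `> 0`.
#' @return An object of class `"grid_solution"`: a list with elements
#'   `cellularity` and `single_copy_depth`.
#' @examples
#' grid_solution(0.68, 15)
#' @export
grid_solution <- function(cellularity, single_copy_depth) {
  if (!is.numeric(cellularity) || length(cellularity) != 1L ||
      is.na(cellularity) || cellularity < 0 || cellularity > 1)
    stop("'cellularity' must be a single value in [0, 1]", call. = FALSE)
  if (!is.numeric(single_copy_depth) || length(single_copy_depth) != 1L ||
      is.na(single_copy_depth) || single_copy_depth <= 0)
    stop("'single_copy_depth' must be a single positive value", call. = FALSE)
  structure(list(cellularity = as.numeric(cellularity),
                 single_copy_depth = as.numeric(single_copy_depth)),
            class = "grid_solution")
}

#' @export
print.grid_solution <- function(x, ...) {
  cat(sprintf("Grid solution: cellularity C = %.4g, single-copy depth D = %.4g\n",
              x$cellularity, x$single_copy_depth))
  invisible(x)
}

#' Allele-specific copy-number state
#'
#' A state holds integer copy counts of the two parental alleles. The
#' minor-allele convention `n2 <= n1` is enforced at construction (the
#' arguments are reordered if needed), so that predicted minor-allele
#' fractions always lie in `[0, 0.5]`.
#'
#' @param n1,n2 Non-negative integer copy counts of the two alleles.
#' @return An object of class `"copy_state"`: a list with integer elements
#'   `n1 >= n2`.
#' @examples
#' copy_state(2, 1)
#' copy_state(1, 4)  # reordered to n1 = 4, n2 = 1
#' @export
copy_state <- function(n1, n2) {
  if (length(n1) != 1L || length(n2) != 1L ||
      is.na(n1) || is.na(n2) || n1 < 0 || n2 < 0 ||
      n1 != round(n1) || n2 != round(n2))
    stop("'n1' and 'n2' must be single non-negative integers", call. = FALSE)
  structure(list(n1 = as.integer(max(n1, n2)), n2 = as.integer(min(n1, n2))),
            class = "copy_state")
}

#' @export
print.copy_state <- function(x, ...) {
  cat(sprintf("Copy state (n1, n2) = (%d, %d), total copy %d\n",
              x$n1, x$n2, x$n1 + x$n2))
  invisible(x)
}

#' Predicted sequencing depth of a copy-number state
#'
#' Expected total depth at a locus in a region with allele-specific copies
#' `(n1, n2)` in a sample of cellularity `C` and single-copy depth `D`:
#' contaminating normal cells contribute two copies each, tumour cells
#' `n1 + n2` copies, so
#' `depth = D * (2 * (1 - C) + (n1 + n2) * C)`.
#'
#' @param solution A [grid_solution()].
#' @param state A [copy_state()], or a two-column matrix/data.frame of
#'   `(n1, n2)` pairs for vectorised evaluation.
#' @return Predicted depth in reads (numeric, one value per state).
#' @examples
#' predicted_depth(grid_solution(0.68, 15), copy_state(2, 2))  # 50.4
#' @export
predicted_depth <- function(solution, state) {
  stopifnot(inherits(solution, "grid_solution"))
  st <- as_state_matrix(state)
  total <- st[, 1L] + st[, 2L]
  C <- solution$cellularity
  unname(solution$single_copy_depth * (2 * (1 - C) + total * C))
}

#' Predicted minor-allele fraction of a copy-number state
#'
#' Expected fraction of reads carrying the minor allele at a
#' germline-heterozygous locus, before accounting for the observational
#' folding at 0.5: each normal cell carries one copy of each allele, each
#' tumour cell `n2` copies of the minor allele out of `n1 + n2`, giving
#' `(1 + C * (n2 - 1)) / (2 + C * (n1 + n2 - 2))`.
#'
#' Under the `n2 <= n1` convention the value lies in `[0, 0.5]`. The state
#' `(0, 0)` in a pure sample (`C = 1`) is degenerate: there are no reads to
#' carry either allele, and the fraction is undefined.
#'
#' @inheritParams predicted_depth
#' @return Predicted minor-allele fraction (numeric, one value per state).
#' @examples
#' predicted_minor_fraction(grid_solution(1, 20), copy_state(4, 1))  # 0.2
#' @export
predicted_minor_fraction <- function(solution, state) {
  stopifnot(inherits(solution, "grid_solution"))
  st <- as_state_matrix(state)
  C <- solution$cellularity
  denom <- 2 + C * (st[, 1L] + st[, 2L] - 2)
  if (any(denom <= 0))
    stop("degenerate state: homozygous deletion (0, 0) in a pure sample ",
         "(C = 1) has no defined allele fraction", call. = FALSE)
  unname((1 + C * (st[, 2L] - 1)) / denom)
}

# Accept a copy_state, a 2-column matrix, or a data.frame with n1/n2.
as_state_matrix <- function(state) {
  if (inherits(state, "copy_state"))
    return(matrix(c(state$n1, state$n2), ncol = 2L))
  if (is.data.frame(state)) {
    stopifnot(all(c("n1", "n2") %in% names(state)))
    state <- cbind(state$n1, state$n2)
  }
  state <- as.matrix(state)
  if (ncol(state) != 2L)
    stop("'state' must be a copy_state or a two-column (n1, n2) matrix",
         call. = FALSE)
  if (any(state < 0) || any(state != round(state)))
    stop("copy numbers must be non-negative integers", call. = FALSE)
  # minor-allele convention
  cbind(pmax(state[, 1L], state[, 2L]), pmin(state[, 1L], state[, 2L]))
}

#' Expected observed minor-allele fraction after folding at 0.5
#'
#' The minor allele is chosen per locus *after* observation: if sampling
#' noise pushes the fraction of the true minor allele above 0.5, the other
#' allele is recorded instead, so the probability mass above 0.5 folds back
#' below it. The recorded mean is therefore biased downward, most strongly
#' at low depth and near balance.
#'
#' With read counts modelled as `X ~ Binomial(d, p)` for true minor
#' fraction `p`, the expectation of the recorded fraction is
#' `E[min(X, d - X)] / d`, computed here by exact enumeration over
#' `k = 0..d`. Fractional depths are rounded to the nearest integer trial
#' count.
#'
#' @param true_fraction True minor-allele fraction(s), in `[0, 0.5]`.
#' @param depth Sequencing depth(s), `>= 1`; rounded to integer.
#' @return Expected observed minor fraction, `<= true_fraction`. Vectorised
#'   over both arguments (recycled to a common length).
#' @examples
#' folded_expected_fraction(0.5, 10)   # 0.376953125
#' folded_expected_fraction(0.5, 1000) # close to 0.5
#' @export
folded_expected_fraction <- function(true_fraction, depth) {
  if (any(is.na(true_fraction)) || any(true_fraction < 0) ||
      any(true_fraction > 0.5))
    stop("'true_fraction' must lie in [0, 0.5]", call. = FALSE)
  d <- as.integer(round(depth))
  if (any(is.na(d)) || any(d < 1L))
    stop("'depth' must be >= 1", call. = FALSE)
  n <- max(length(true_fraction), length(d))
  p <- rep_len(true_fraction, n)
  d <- rep_len(d, n)
  vapply(seq_len(n), function(i) {
    k <- 0:d[i]
    sum(pmin(k, d[i] - k) * stats::dbinom(k, d[i], p[i])) / d[i]
  }, numeric(1))
}

#' Build the predicted copy-number lattice for a solution
#'
#' Enumerates every allele-specific copy-number state with
#' `n1 + n2 <= max_total_copy` and `n2 <= n1`, and computes each state's
#' predicted depth, predicted (raw) minor-allele fraction, and folded
#' expected fraction. The folding is evaluated at the state's predicted
#' depth rounded to the nearest integer. Degenerate states (the `(0, 0)`
#' state in a pure sample, where no allele fraction exists) are omitted
#' with a message.
#'
#' @param solution A [grid_solution()].
#' @param max_total_copy Largest total copy number to enumerate (default 8).
#' @param fold If `TRUE` (default), `folded_fraction` is the
#'   folded-binomial expectation at the node's depth; if `FALSE` it equals
#'   `predicted_fraction` (the raw lattice).
#' @return A data.frame of class `"baf_grid"` with columns `n1`, `n2`,
#'   `total_copy`, `predicted_depth`, `predicted_fraction`,
#'   `folded_fraction`.
#' @examples
#' build_grid(grid_solution(0.68, 15), max_total_copy = 4)
#' @export
build_grid <- function(solution, max_total_copy = 8L, fold = TRUE) {
  stopifnot(inherits(solution, "grid_solution"))
  if (max_total_copy < 1L)
    stop("'max_total_copy' must be >= 1", call. = FALSE)
  states <- enumerate_states(max_total_copy)
  C <- solution$cellularity
  degenerate <- C >= 1 & states[, 1L] + states[, 2L] == 0L
  if (any(degenerate)) {
    message("omitting ", sum(degenerate),
            " degenerate state(s) with no allele fraction: (0, 0) at C = 1")
    states <- states[!degenerate, , drop = FALSE]
  }
  depth <- predicted_depth(solution, states)
  frac <- predicted_minor_fraction(solution, states)
  folded <- if (fold) {
    folded_expected_fraction(frac, pmax(1, round(depth)))
  } else frac
  out <- data.frame(n1 = states[, 1L], n2 = states[, 2L],
                    total_copy = states[, 1L] + states[, 2L],
                    predicted_depth = depth,
                    predicted_fraction = frac,
                    folded_fraction = folded)
  class(out) <- c("baf_grid", "data.frame")
  attr(out, "solution") <- solution
  out
}

# All (n1, n2) with n2 <= n1 and n1 + n2 <= max_total; includes (0, 0).
enumerate_states <- function(max_total) {
  pairs <- expand.grid(n2 = 0:max_total, n1 = 0:max_total)
  pairs <- pairs[pairs$n2 <= pairs$n1 & pairs$n1 + pairs$n2 <= max_total, ]
  m <- cbind(pairs$n1, pairs$n2)
  m[order(m[, 1L] + m[, 2L], m[, 2L]), , drop = FALSE]
}

#' Write a predicted grid to TSV
#'
#' @param grid A grid from [build_grid()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_grid <- function(grid, path) {
  stopifnot(inherits(grid, "baf_grid"))
  utils::write.table(
    grid[, c("n1", "n2", "predicted_depth", "predicted_fraction",
             "folded_fraction")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
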