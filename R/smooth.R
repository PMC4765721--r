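#' Running median/mean smoothing along the genome
#'
#' Applies a running median (default) or mean to depth and minor-allele
#' fraction, independently per chromosome in positional order. Raw
#' per-locus values are noisy at realistic depths; smoothing over `window`
#' neighbouring loci concentrates each clonal copy-number state into a
#' tight mode on the (depth, fraction) plane. At chromosome ends the
#' window shrinks symmetrically (so `window = 1` is the identity and every
#' locus yields exactly one output).
#'
#' Larger windows suppress more noise but average across copy-number
#' breakpoints when few loci are used, blending distinct states; with
#' sparse loci a smaller window (e.g. 11) preserves state separation at
#' the cost of noise.
#'
#' @param obs Locus observations (`chrom`, `pos`, `depth`,
#'   `minor_fraction`).
#' @param window Odd positive integer window length in loci (default 51).
#' @param statistic `"median"` (default) or `"mean"`.
#' @return A data.frame `chrom`, `pos`, `smoothed_depth`,
#'   `smoothed_fraction`, one row per input row, sorted by (chrom, pos).
#' @export
running_smooth <- function(obs, window = 51L, statistic = c("median", "mean")) {
  statistic <- match.arg(statistic)
  window <- as.integer(window)
  if (is.na(window) || window < 1L || window %% 2L == 0L)
    stop("'window' must be an odd positive integer", call. = FALSE)
  obs <- obs[order(obs$chrom, obs$pos), , drop = FALSE]
  fun <- if (statistic == "median") stats::median else mean
  smooth_one <- function(x) {
    n <- length(x)
    half <- (window - 1L) %/% 2L
    vapply(seq_len(n), function(i) {
      k <- min(half, i - 1L, n - i)
      fun(x[(i - k):(i + k)])
    }, numeric(1))
  }
  pieces <- lapply(split(seq_len(nrow(obs)), obs$chrom), function(idx) {
    data.frame(chrom = obs$chrom[idx], pos = obs$pos[idx],
               smoothed_depth = smooth_one(obs$depth[idx]),
               smoothed_fraction = smooth_one(obs$minor_fraction[idx]))
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}
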