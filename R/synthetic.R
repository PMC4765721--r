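#' Segmented clonal copy-number profile
#'
#' Describes the generating truth for simulations: a set of genomic
#' segments, each with an allele-specific copy-number state and a number
#' of candidate heterozygous loci. Segments may be placed explicitly
#' (`start`/`end`) or laid end-to-end automatically with a fixed locus
#' spacing.
#'
#' @param n1,n2 Integer copy numbers per segment (recycled pairwise;
#'   reordered so `n1 >= n2`).
#' @param n_loci Number of loci per segment.
#' @param chrom Chromosome name(s) (default `"chr1"`, recycled).
#' @param start,end Optional 1-based segment bounds. When omitted,
#'   segments are placed consecutively with `locus_spacing` bases between
#'   loci.
#' @param locus_spacing Spacing used for automatic layout (default 1000).
#' @return A data.frame of class `"segment_profile"` with columns `chrom`,
#'   `start`, `end`, `n1`, `n2`, `n_loci`.
#' @export
segment_profile <- function(n1, n2, n_loci, chrom = "chr1", start = NULL,
                            end = NULL, locus_spacing = 1000L) {
  k <- max(length(n1), length(n2), length(n_loci), length(chrom),
           length(start), length(end))
  n1 <- rep_len(as.integer(n1), k); n2 <- rep_len(as.integer(n2), k)
  n_loci <- rep_len(as.integer(n_loci), k)
  chrom <- rep_len(as.character(chrom), k)
  if (any(n1 < 0 | n2 < 0 | n_loci < 0))
    stop("copy numbers and locus counts must be non-negative", call. = FALSE)
  swap <- n2 > n1
  tmp <- n1[swap]; n1[swap] <- n2[swap]; n2[swap] <- tmp
  if (is.null(start) != is.null(end))
    stop("give both 'start' and 'end', or neither", call. = FALSE)
  if (is.null(start)) {
    start <- integer(k); end <- integer(k)
    for (ch in unique(chrom)) {
      idx <- which(chrom == ch)
      cursor <- 1L
      for (i in idx) {
        start[i] <- cursor
        end[i] <- cursor + max(0L, n_loci[i] - 1L) * as.integer(locus_spacing)
        cursor <- end[i] + as.integer(locus_spacing)
      }
    }
  } else {
    start <- rep_len(as.integer(start), k); end <- rep_len(as.integer(end), k)
    if (any(start < 1L | end < start))
      stop("segments need 1 <= start <= end", call. = FALSE)
    for (ch in unique(chrom)) {
      idx <- which(chrom == ch)
      o <- idx[order(start[idx])]
      if (length(o) > 1L && any(start[o][-1L] <= end[o][-length(o)]))
        stop("segments overlap on ", ch, call. = FALSE)
    }
  }
  out <- data.frame(chrom = chrom, start = start, end = end,
                    n1 = n1, n2 = n2, n_loci = n_loci)
  class(out) <- c("segment_profile", "data.frame")
  out
}

#' Generating truth for a simulation
#'
#' Bundles a [segment_profile()], the generating [grid_solution()], the
#' seed, and the depth-noise model.
#'
#' @param profile A [segment_profile()].
#' @param solution The generating [grid_solution()].
#' @param seed Integer seed (default 1).
#' @param depth_noise `"poisson"` (default): per-locus depth drawn
#'   Poisson around the state's predicted mean; `"fixed"`: the rounded
#'   predicted mean at every locus.
#' @return An object of class `"sim_truth"`.
#' @export
sim_truth <- function(profile, solution, seed = 1L,
                      depth_noise = c("poisson", "fixed")) {
  stopifnot(inherits(profile, "segment_profile"),
            inherits(solution, "grid_solution"))
  structure(list(profile = profile, solution = solution,
                 seed = as.integer(seed),
                 depth_noise = match.arg(depth_noise)),
            class = "sim_truth")
}

#' Simulate locus observations from a known truth
#'
#' Generates per-locus depths and minor-allele fractions under the clonal
#' copy-number model. For a locus in state `(n1, n2)` at cellularity `C`
#' and single-copy depth `D`:
#' \itemize{
#'   \item total depth is drawn `Poisson` with mean
#'     `D * (2(1 - C) + (n1 + n2) C)` (or fixed at its rounded value);
#'   \item reads carrying one fixed phased allele are drawn
#'     `Binomial(depth, p)` with
#'     `p = (1 - C + C * n2) / (2(1 - C) + C * (n1 + n2))`, the phased
#'     minor-lineage fraction;
#'   \item the recorded `minor_fraction` is `min(x, depth - x) / depth` —
#'     the minor allele is chosen after observation, so the folding of
#'     fractions above 0.5 arises naturally from the sampling, exactly as
#'     it does in real data, and is never injected.
#' }
#' Zero-depth loci are dropped. Identical truth (including seed) gives
#' identical output; the caller's RNG state is untouched.
#'
#' @param truth A [sim_truth()].
#' @return A data.frame with columns `chrom`, `pos`, `depth`,
#'   `minor_fraction`, plus the bookkeeping columns `phased_count` (reads
#'   carrying the fixed phased allele), `n1`, `n2`. The truth is attached
#'   as attribute `"truth"`.
#' @export
simulate_observations <- function(truth) {
  stopifnot(inherits(truth, "sim_truth"))
  prof <- truth$profile
  sol <- truth$solution
  if (sol$cellularity >= 1 && any(prof$n1 + prof$n2 == 0L & prof$n_loci > 0L))
    stop("degenerate segment: state (0, 0) at cellularity 1 yields no reads ",
         "and no allele fraction", call. = FALSE)
  pieces <- with_local_seed(truth$seed, {
    lapply(seq_len(nrow(prof)), function(i) {
      n <- prof$n_loci[i]
      if (n == 0L) return(NULL)
      pos <- if (n == 1L) prof$start[i] else
        as.integer(round(seq(prof$start[i], prof$end[i], length.out = n)))
      state <- c(prof$n1[i], prof$n2[i])
      mu <- predicted_depth(sol, matrix(state, ncol = 2L))
      p <- predicted_minor_fraction(sol, matrix(state, ncol = 2L))
      depth <- if (truth$depth_noise == "poisson") stats::rpois(n, mu)
               else rep(max(1L, as.integer(round(mu))), n)
      x <- stats::rbinom(n, depth, p)
      data.frame(chrom = prof$chrom[i], pos = pos, depth = depth,
                 minor_fraction = ifelse(depth > 0,
                                         pmin(x, depth - x) / depth, NA_real_),
                 phased_count = x, n1 = prof$n1[i], n2 = prof$n2[i])
    })
  })
  obs <- do.call(rbind, pieces)
  if (is.null(obs) || nrow(obs) == 0L)
    stop("profile contains no loci", call. = FALSE)
  dropped <- obs$depth == 0L
  if (any(dropped))
    message(sum(dropped), " zero-depth locus/loci dropped")
  obs <- obs[!dropped, , drop = FALSE]
  obs <- obs[order(obs$chrom, obs$pos), , drop = FALSE]
  rownames(obs) <- NULL
  attr(obs, "truth") <- truth
  obs
}

#' Write a SAM fixture realising a simulated truth
#'
#' Emits a coordinate-sorted SAM text file whose reads reproduce, base for
#' base, the allele counts drawn by [simulate_observations()] for the same
#' truth, plus the matching candidate-loci TSV. Each locus gets `depth`
#' reads covering it — `phased_count` carrying the alternate base `C`, the
#' rest the reference base `A` — with mapping and base qualities above the
#' default scan filters, so [pileup_at_loci()] on the fixture recovers the
#' simulated counts exactly. Optionally, low-mapping-quality reads are
#' added at every locus to exercise the filters.
#'
#' Intended for small test fixtures only: at most `1e5` reads, and locus
#' spacing must exceed the read length so reads never straddle two loci.
#'
#' @param truth A [sim_truth()].
#' @param out_path Output SAM path (extension `.sam`).
#' @param loci_path Output loci TSV path (default: `out_path` with
#'   `.loci.tsv`).
#' @param reference_length Length recorded for each contig; default: far
#'   enough past the last read.
#' @param read_length Read length in bases (default 20).
#' @param mapq Mapping quality of ordinary reads (default 60).
#' @param n_lowqual Extra reference-base reads per locus at mapping
#'   quality `lowqual_mapq` (default 0).
#' @param lowqual_mapq Mapping quality of the extra reads (default 5).
#' @return Invisibly, a list with `sam`, `loci` (paths) and
#'   `observations` (the simulated table the fixture realises).
#' @export
write_sam_fixture <- function(truth, out_path,
                              loci_path = sub("\\.sam$", ".loci.tsv",
                                              out_path),
                              reference_length = NULL, read_length = 20L,
                              mapq = 60L, n_lowqual = 0L,
                              lowqual_mapq = 5L) {
  obs <- suppressMessages(simulate_observations(truth))
  n_reads <- sum(obs$depth) + n_lowqual * nrow(obs)
  if (n_reads > 1e5)
    stop("fixture too large: ", n_reads, " reads (limit 1e5)", call. = FALSE)
  for (ch in unique(obs$chrom)) {
    p <- sort(obs$pos[obs$chrom == ch])
    if (length(p) > 1L && min(diff(p)) <= read_length)
      stop("locus spacing on ", ch, " must exceed the read length (",
           read_length, ")", call. = FALSE)
  }
  chroms <- unique(obs$chrom)
  ref_len <- if (is.null(reference_length))
    vapply(chroms, function(ch) max(obs$pos[obs$chrom == ch]) +
             read_length + 10L, numeric(1))
  else rep_len(reference_length, length(chroms))

  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", chroms, as.integer(ref_len)))
  qual <- strrep("I", read_length)
  ref_seq <- strrep("A", read_length)
  lines <- vector("list", nrow(obs))
  for (i in seq_len(nrow(obs))) {
    pos <- obs$pos[i]
    start <- max(1L, pos - read_length %/% 2L)
    offset <- pos - start + 1L
    alt_seq <- ref_seq
    substr(alt_seq, offset, offset) <- "C"
    n_alt <- obs$phased_count[i]
    n_ref <- obs$depth[i] - n_alt
    seqs <- c(rep(alt_seq, n_alt), rep(ref_seq, n_ref))
    mapqs <- rep(mapq, obs$depth[i])
    if (n_lowqual > 0L) {
      seqs <- c(seqs, rep(ref_seq, n_lowqual))
      mapqs <- c(mapqs, rep(lowqual_mapq, n_lowqual))
    }
    lines[[i]] <- sprintf(
      "r%s_%d_%d\t0\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t%s",
      obs$chrom[i], pos, seq_along(seqs), obs$chrom[i], start, mapqs,
      read_length, seqs, qual)
  }
  writeLines(c(header, unlist(lines)), out_path)
  utils::write.table(
    data.frame(chrom = obs$chrom, pos = obs$pos, ref = "A", alt = "C"),
    loci_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(sam = out_path, loci = loci_path, observations = obs))
}
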