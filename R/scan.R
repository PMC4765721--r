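#' Load a candidate heterozygous-loci table
#'
#' Reads a TSV of candidate germline-heterozygous sites with columns
#' `chrom`, `pos` (1-based) and optionally `ref`, `alt`. A header line is
#' detected by a non-numeric position field. Duplicate (chrom, pos) rows
#' are dropped with a warning and the result is sorted by chromosome then
#' position.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with columns `chrom`, `pos` and, when present in
#'   the file, `ref` and `alt`.
#' @export
load_candidate_loci <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no loci: '", path, "' is empty", call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  start <- 1L
  if (suppressWarnings(is.na(as.numeric(fields[[1L]][2L])))) start <- 2L
  if (start > length(lines)) stop("no loci: '", path, "' has only a header",
                                  call. = FALSE)
  n_col <- length(fields[[start]])
  rows <- lapply(start:length(lines), function(i) {
    f <- fields[[i]]
    if (length(f) < 2L)
      stop("malformed loci row at line ", i, ": fewer than 2 fields",
           call. = FALSE)
    pos <- suppressWarnings(as.numeric(f[2L]))
    if (is.na(pos) || pos < 1 || pos != round(pos))
      stop("malformed loci row at line ", i, ": position '", f[2L],
           "' is not a positive integer", call. = FALSE)
    f
  })
  loci <- data.frame(chrom = vapply(rows, `[`, "", 1L),
                     pos = as.integer(vapply(rows, `[`, "", 2L)))
  if (n_col >= 4L) {
    loci$ref <- vapply(rows, function(f) if (length(f) >= 3L) f[3L] else NA_character_, "")
    loci$alt <- vapply(rows, function(f) if (length(f) >= 4L) f[4L] else NA_character_, "")
  }
  dup <- duplicated(loci[c("chrom", "pos")])
  if (any(dup)) {
    warning(sum(dup), " duplicate locus/loci dropped", call. = FALSE)
    loci <- loci[!dup, , drop = FALSE]
  }
  loci <- loci[order(loci$chrom, loci$pos), , drop = FALSE]
  rownames(loci) <- NULL
  loci
}

# Resolve a BAM/SAM path to an indexed BAM, converting SAM text fixtures on
# the fly. A missing BAM index is an error (we never build one silently for
# a user's BAM: an unindexed file usually means an unsorted one).
resolve_alignment <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path, call. = FALSE)
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                            indexDestination = TRUE)
    return(bam)
  }
  idx <- c(paste0(path, ".bai"), sub("\\.bam$", ".bai", path))
  if (!any(file.exists(idx)))
    stop("no index found for '", path, "'. Create one with ",
         "Rsamtools::indexBam(\"", path, "\") or `samtools index` ",
         "(the file must be coordinate-sorted first)", call. = FALSE)
  path
}

# Error on chr1-vs-1 naming mismatches instead of silently translating;
# warn-and-drop loci on contigs genuinely absent from the header.
check_chrom_dialect <- function(loci, targets) {
  present <- unique(loci$chrom) %in% targets
  if (!any(present)) {
    stripped_loci <- sub("^chr", "", unique(loci$chrom))
    stripped_targets <- sub("^chr", "", targets)
    if (any(stripped_loci %in% stripped_targets)) {
      loci_style <- if (any(grepl("^chr", loci$chrom))) "'chr1'" else "'1'"
      bam_style <- if (any(grepl("^chr", targets))) "'chr1'" else "'1'"
      stop("chromosome naming mismatch: loci use ", loci_style,
           "-style names but the alignment header uses ", bam_style,
           "-style names; rename one to match", call. = FALSE)
    }
  }
  missing <- setdiff(unique(loci$chrom), targets)
  if (length(missing) > 0L)
    warning("dropping loci on contig(s) absent from the alignment header: ",
            paste(missing, collapse = ", "), call. = FALSE)
  loci[loci$chrom %in% targets, , drop = FALSE]
}

#' Count bases at candidate loci in an alignment file
#'
#' Interrogates a coordinate-sorted, indexed BAM (or a SAM text file, which
#' is converted to a temporary BAM) at each candidate locus and returns
#' per-nucleotide read counts. Reads below the mapping-quality filter,
#' bases below the base-quality filter, and duplicate-flagged or secondary
#' alignments are excluded.
#'
#' @param alignment_path Path to a BAM (indexed) or SAM file.
#' @param loci Candidate loci, as from [load_candidate_loci()].
#' @param min_mapq Minimum mapping quality (default 30).
#' @param min_baseq Minimum base quality (default 20).
#' @return A data.frame with one row per locus: `chrom`, `pos`, counts
#'   `A`, `C`, `G`, `T`, and `depth` (their sum). Loci with no coverage get
#'   zero counts; loci on contigs absent from the header are dropped with a
#'   warning.
#' @export
pileup_at_loci <- function(alignment_path, loci, min_mapq = 30L,
                           min_baseq = 20L) {
  bam <- resolve_alignment(alignment_path)
  header <- Rsamtools::scanBamHeader(bam)[[1L]]$targets
  loci <- check_chrom_dialect(loci, names(header))
  if (nrow(loci) == 0L) stop("no loci remain on the alignment's contigs",
                             call. = FALSE)
  which <- GenomicRanges::GRanges(loci$chrom,
                                  IRanges::IRanges(loci$pos, loci$pos))
  sbp <- Rsamtools::ScanBamParam(
    which = which,
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isDuplicate = FALSE,
                                  isSecondaryAlignment = FALSE))
  pp <- Rsamtools::PileupParam(
    max_depth = 100000L, min_base_quality = as.integer(min_baseq),
    min_mapq = as.integer(min_mapq), min_nucleotide_depth = 0L,
    distinguish_strands = FALSE, distinguish_nucleotides = TRUE,
    ignore_query_Ns = TRUE, include_deletions = FALSE,
    include_insertions = FALSE)
  p <- Rsamtools::pileup(bam, scanBamParam = sbp, pileupParam = pp)

  out <- data.frame(chrom = loci$chrom, pos = loci$pos,
                    A = 0L, C = 0L, G = 0L, T = 0L)
  if (nrow(p) > 0L) {
    key <- paste(as.character(p$seqnames), p$pos)
    out_key <- paste(out$chrom, out$pos)
    for (nt in c("A", "C", "G", "T")) {
      sel <- p$nucleotide == nt
      if (any(sel)) {
        counts <- tapply(p$count[sel], key[sel], sum)
        idx <- match(names(counts), out_key)
        ok <- !is.na(idx)
        out[[nt]][idx[ok]] <- as.integer(counts[ok])
      }
    }
  }
  out$depth <- out$A + out$C + out$G + out$T
  out
}

#' Call a locus heterozygous from normal-sample base counts
#'
#' A locus is called heterozygous when its depth reaches `min_depth` and
#' the second-most-frequent base accounts for a fraction of the depth
#' within `[lo_fraction, hi_fraction]`.
#'
#' @param counts A pileup data.frame from [pileup_at_loci()] (columns
#'   `A`, `C`, `G`, `T`, `depth`).
#' @param min_depth Minimum depth (default 15).
#' @param lo_fraction,hi_fraction Allowed band for the second allele's
#'   fraction (defaults 0.3 and 0.7).
#' @return Logical vector, one value per row of `counts`.
#' @export
call_heterozygous <- function(counts, min_depth = 15L, lo_fraction = 0.3,
                              hi_fraction = 0.7) {
  stopifnot(lo_fraction > 0, lo_fraction < hi_fraction, hi_fraction < 1)
  m <- as.matrix(counts[, c("A", "C", "G", "T")])
  second <- apply(m, 1L, function(x) sort(x, decreasing = TRUE)[2L])
  frac <- ifelse(counts$depth > 0, second / counts$depth, 0)
  counts$depth >= min_depth & frac >= lo_fraction & frac <= hi_fraction
}

# Top two bases per row of an A/C/G/T count matrix: indices and counts.
top_two_bases <- function(m) {
  o <- t(apply(m, 1L, order, decreasing = TRUE))
  n <- nrow(m)
  first <- m[cbind(seq_len(n), o[, 1L])]
  second <- m[cbind(seq_len(n), o[, 2L])]
  list(i1 = o[, 1L], i2 = o[, 2L], c1 = first, c2 = second)
}

#' Scan a tumour/normal pair for depth and minor-allele fraction
#'
#' Counts bases in both samples at the candidate loci, calls heterozygous
#' sites in the normal, and records the tumour's depth and minor-allele
#' fraction at those sites. The fraction is computed over the two alleles
#' identified in the normal: `minor_fraction = min(f, 1 - f)` where `f` is
#' the tumour fraction of one of the normal's het alleles among reads
#' carrying either. Tumour loci below `min_depth` are dropped.
#'
#' @param tumour_path,normal_path Paths to the tumour and matched-normal
#'   alignment files.
#' @inheritParams pileup_at_loci
#' @inheritParams call_heterozygous
#' @return A data.frame of locus observations: `chrom`, `pos`, `depth`,
#'   `minor_fraction`.
#' @export
tumour_normal_scan <- function(tumour_path, normal_path, loci,
                               min_mapq = 30L, min_baseq = 20L,
                               min_depth = 15L, lo_fraction = 0.3,
                               hi_fraction = 0.7) {
  normal <- pileup_at_loci(normal_path, loci, min_mapq, min_baseq)
  het <- call_heterozygous(normal, min_depth, lo_fraction, hi_fraction)
  normal <- normal[het, , drop = FALSE]
  if (nrow(normal) == 0L)
    stop("no heterozygous loci called in the normal sample", call. = FALSE)
  tumour <- suppressWarnings(
    pileup_at_loci(tumour_path, normal[, c("chrom", "pos")],
                   min_mapq, min_baseq))
  key_t <- paste(tumour$chrom, tumour$pos)
  key_n <- paste(normal$chrom, normal$pos)
  normal <- normal[match(key_t, key_n), , drop = FALSE]

  bases <- c("A", "C", "G", "T")
  tt <- top_two_bases(as.matrix(normal[, bases]))
  tm <- as.matrix(tumour[, bases])
  n <- nrow(tumour)
  a1 <- tm[cbind(seq_len(n), tt$i1)]
  a2 <- tm[cbind(seq_len(n), tt$i2)]
  two_total <- a1 + a2
  keep <- tumour$depth >= min_depth & two_total > 0
  data.frame(chrom = tumour$chrom[keep], pos = tumour$pos[keep],
             depth = tumour$depth[keep],
             minor_fraction = pmin(a1[keep], a2[keep]) / two_total[keep])
}

#' Scan a cell line (no matched normal) with LOH down-sampling
#'
#' Without a germline reference, a heterozygous site that has undergone
#' loss of heterozygosity is indistinguishable at a single locus from a
#' germline-homozygous site, and the mass of homozygous-looking loci would
#' drown out the informative heterozygous ones on a density plot. Loci
#' whose minor fraction falls below `loh_threshold` are therefore randomly
#' retained at rate `loh_keep_fraction` (reproducibly, under `seed`);
#' all other sufficiently covered loci are kept.
#'
#' The minor fraction is computed over the two most frequent bases at the
#' locus.
#'
#' @inheritParams tumour_normal_scan
#' @param loh_threshold Minor-fraction threshold below which a locus is
#'   treated as LOH-like (default 0.1).
#' @param loh_keep_fraction Retention rate for LOH-like loci (default
#'   0.05).
#' @param seed Integer seed for the down-sampling.
#' @return A data.frame of locus observations: `chrom`, `pos`, `depth`,
#'   `minor_fraction`.
#' @export
cellline_scan <- function(tumour_path, loci, min_mapq = 30L,
                          min_baseq = 20L, min_depth = 15L,
                          loh_threshold = 0.1, loh_keep_fraction = 0.05,
                          seed = 1L) {
  stopifnot(loh_threshold > 0, loh_threshold < 0.5,
            loh_keep_fraction > 0, loh_keep_fraction <= 1)
  counts <- pileup_at_loci(tumour_path, loci, min_mapq, min_baseq)
  counts <- counts[counts$depth >= min_depth, , drop = FALSE]
  if (nrow(counts) == 0L) stop("no loci pass the depth filter", call. = FALSE)
  tt <- top_two_bases(as.matrix(counts[, c("A", "C", "G", "T")]))
  two_total <- tt$c1 + tt$c2
  minor <- ifelse(two_total > 0, tt$c2 / two_total, 0)
  obs <- data.frame(chrom = counts$chrom, pos = counts$pos,
                    depth = counts$depth, minor_fraction = minor)
  loh_like <- obs$minor_fraction < loh_threshold
  if (any(loh_like) && loh_keep_fraction < 1) {
    keep <- rep(TRUE, nrow(obs))
    keep[loh_like] <- with_local_seed(seed, {
      stats::runif(sum(loh_like)) < loh_keep_fraction
    })
    message("down-sampled ", sum(loh_like), " LOH-like loci (minor fraction < ",
            loh_threshold, ") to ", sum(keep & loh_like), " at rate ",
            loh_keep_fraction)
    obs <- obs[keep, , drop = FALSE]
  }
  rownames(obs) <- NULL
  obs
}

# Run code under a given seed, restoring the caller's RNG state after.
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Read and write locus-observation tables
#'
#' Locus observations are plain TSV with header columns `chrom`, `pos`,
#' `depth`, `minor_fraction` — the interchange format between the scanning,
#' smoothing and fitting steps.
#'
#' @param path File path.
#' @param obs A locus-observation data.frame.
#' @return `read_observations` returns the data.frame;
#'   `write_observations` returns `path` invisibly.
#' @export
read_observations <- function(path) {
  obs <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "depth", "minor_fraction")
  if (!all(need %in% names(obs)))
    stop("observation table must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  obs[, need]
}

#' @rdname read_observations
#' @export
write_observations <- function(obs, path) {
  utils::write.table(obs[, c("chrom", "pos", "depth", "minor_fraction")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
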