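test_that("candidate loci load, deduplicate and sort", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tref\talt",
               "chr2\t500\tA\tC",
               "chr1\t900\tA\tG",
               "chr2\t500\tA\tC"), path)
  expect_warning(loci <- load_candidate_loci(path), "duplicate")
  expect_equal(nrow(loci), 2L)
  expect_equal(loci$chrom, c("chr1", "chr2"))
  expect_equal(loci$pos, c(900L, 500L))

  # headerless two-column files work too
  writeLines(c("chr1\t100", "chr1\t200"), path)
  expect_equal(nrow(load_candidate_loci(path)), 2L)

  writeLines(character(0), path)
  expect_error(load_candidate_loci(path), "no loci")
  writeLines(c("chrom\tpos", "chr1\tnotanumber"), path)
  expect_error(load_candidate_loci(path), "line 2")
})

test_that("pileup on a SAM fixture reproduces the simulated counts", {
  truth <- sim_truth(segment_profile(n1 = c(1, 2), n2 = c(1, 0),
                                     n_loci = c(8, 8)),
                     grid_solution(0.7, 12), seed = 11)
  fx <- tmp_sam_fixture(truth)
  loci <- load_candidate_loci(fx$loci)
  pc <- pileup_at_loci(fx$sam, loci)
  expect_equal(pc$depth, fx$observations$depth)
  expect_equal(pc$C, fx$observations$phased_count)
  expect_equal(pc$A, fx$observations$depth - fx$observations$phased_count)
  expect_true(all(pc$G == 0L & pc$T == 0L))
})

test_that("mapping-quality filtering drops low-quality reads", {
  truth <- sim_truth(segment_profile(n1 = 1, n2 = 1, n_loci = 5),
                     grid_solution(1, 10), seed = 4, depth_noise = "fixed")
  fx <- tmp_sam_fixture(truth, n_lowqual = 3L)
  loci <- load_candidate_loci(fx$loci)
  # default min_mapq = 30 excludes the three mapq-5 reads at each locus
  filtered <- pileup_at_loci(fx$sam, loci)
  expect_equal(filtered$depth, fx$observations$depth)
  # lowering the filter brings them back
  unfiltered <- pileup_at_loci(fx$sam, loci, min_mapq = 0)
  expect_equal(unfiltered$depth, fx$observations$depth + 3L)
})

test_that("uncovered and unknown loci are handled explicitly", {
  truth <- sim_truth(segment_profile(n1 = 1, n2 = 1, n_loci = 4),
                     grid_solution(1, 10), seed = 2)
  fx <- tmp_sam_fixture(truth)
  loci <- load_candidate_loci(fx$loci)
  # a covered-chromosome position with no reads: zero counts
  extra <- rbind(loci[, c("chrom", "pos")],
                 data.frame(chrom = "chr1", pos = max(loci$pos) + 5000L))
  pc <- pileup_at_loci(fx$sam, extra)
  expect_equal(pc$depth[nrow(pc)], 0L)
  # a contig absent from the header: dropped with a warning
  extra2 <- rbind(loci[, c("chrom", "pos")],
                  data.frame(chrom = "chr9", pos = 100L))
  expect_warning(pc2 <- pileup_at_loci(fx$sam, extra2), "chr9")
  expect_equal(nrow(pc2), nrow(loci))
  # wholesale chr-prefix mismatch: an error naming both dialects
  bare <- data.frame(chrom = sub("^chr", "", loci$chrom), pos = loci$pos)
  expect_error(pileup_at_loci(fx$sam, bare), "naming mismatch")
})

test_that("a BAM without an index gets an instructive error", {
  truth <- sim_truth(segment_profile(n1 = 1, n2 = 1, n_loci = 3),
                     grid_solution(1, 10), seed = 5)
  dir <- withr::local_tempdir()
  fx <- tmp_sam_fixture(truth, dir = dir)
  bam <- Rsamtools::asBam(fx$sam, file.path(dir, "noindex"),
                          indexDestination = FALSE)
  expect_error(pileup_at_loci(bam, load_candidate_loci(fx$loci)), "index")
})

test_that("heterozygous calling applies depth and band thresholds", {
  counts <- data.frame(A = c(22L, 39L, 3L), C = c(18L, 1L, 2L),
                       G = 0L, T = 0L, depth = c(40L, 40L, 5L))
  expect_equal(call_heterozygous(counts), c(TRUE, FALSE, FALSE))
})

test_that("tumour/normal scan records the tumour minor fraction at normal-het sites", {
  # normal: pure diploid het everywhere; tumour: LOH and unbalanced states
  prof_t <- segment_profile(n1 = c(2, 2, 1), n2 = c(0, 1, 1),
                            n_loci = c(10, 10, 10))
  prof_n <- segment_profile(n1 = rep(1, 3), n2 = rep(1, 3),
                            n_loci = c(10, 10, 10))
  dir <- withr::local_tempdir()
  fx_t <- write_sam_fixture(sim_truth(prof_t, grid_solution(0.8, 20),
                                      seed = 21, depth_noise = "fixed"),
                            file.path(dir, "tumour.sam"))
  fx_n <- write_sam_fixture(sim_truth(prof_n, grid_solution(0, 20), seed = 22,
                                      depth_noise = "fixed"),
                            file.path(dir, "normal.sam"))
  loci <- load_candidate_loci(fx_t$loci)
  obs <- tumour_normal_scan(fx_t$sam, fx_n$sam, loci)
  # every output locus was called het in the normal
  norm_counts <- pileup_at_loci(fx_n$sam, loci)
  het_pos <- norm_counts$pos[call_heterozygous(norm_counts)]
  expect_true(all(obs$pos %in% het_pos))
  # fractions equal the fixture's realised counts, folded below 0.5
  truth_obs <- fx_t$observations
  m <- match(obs$pos, truth_obs$pos)
  expect_equal(obs$depth, truth_obs$depth[m])
  expect_equal(obs$minor_fraction,
               pmin(truth_obs$phased_count[m],
                    truth_obs$depth[m] - truth_obs$phased_count[m]) /
                 truth_obs$depth[m])
  expect_true(all(obs$minor_fraction <= 0.5))
})

test_that("loci homozygous in the normal are excluded", {
  # normal carries an LOH segment: those loci look homozygous and must not
  # contribute observations
  prof_n <- segment_profile(n1 = c(1, 2), n2 = c(1, 0), n_loci = c(8, 8))
  prof_t <- segment_profile(n1 = c(2, 2), n2 = c(1, 1), n_loci = c(8, 8))
  dir <- withr::local_tempdir()
  fx_t <- write_sam_fixture(sim_truth(prof_t, grid_solution(0.9, 20),
                                      seed = 31, depth_noise = "fixed"),
                            file.path(dir, "tumour.sam"))
  fx_n <- write_sam_fixture(sim_truth(prof_n, grid_solution(1, 20), seed = 32,
                                      depth_noise = "fixed"),
                            file.path(dir, "normal.sam"))
  loci <- load_candidate_loci(fx_t$loci)
  obs <- tumour_normal_scan(fx_t$sam, fx_n$sam, loci)
  hom_pos <- fx_n$observations$pos[fx_n$observations$n2 == 0L]
  expect_true(all(!obs$pos %in% hom_pos))
  expect_gt(nrow(obs), 0L)
})

test_that("cell-line scan down-samples LOH-like loci reproducibly", {
  # half the loci LOH (minor fraction ~ 0), half balanced
  prof <- segment_profile(n1 = c(1, 1), n2 = c(0, 1), n_loci = c(60, 60))
  truth <- sim_truth(prof, grid_solution(1, 20), seed = 41,
                     depth_noise = "fixed")
  fx <- tmp_sam_fixture(truth)
  loci <- load_candidate_loci(fx$loci)
  suppressMessages({
    a <- cellline_scan(fx$sam, loci, loh_keep_fraction = 0.2, seed = 7)
    b <- cellline_scan(fx$sam, loci, loh_keep_fraction = 0.2, seed = 7)
    c2 <- cellline_scan(fx$sam, loci, loh_keep_fraction = 0.2, seed = 8)
  })
  expect_identical(a, b)                       # same seed, same set
  expect_false(identical(a$pos, c2$pos))       # different seed, different set
  # balanced loci all retained; LOH-like loci thinned
  loh_pos <- fx$observations$pos[fx$observations$n2 == 0L]
  expect_true(all(setdiff(fx$observations$pos, loh_pos) %in% a$pos))
  expect_lt(sum(a$pos %in% loh_pos), length(loh_pos))
  # keep rate 1 leaves everything
  full <- cellline_scan(fx$sam, loci, loh_keep_fraction = 1, seed = 7)
  expect_equal(nrow(full), nrow(fx$observations))
  # balanced-only input: nothing to down-sample
  prof_b <- segment_profile(n1 = 1, n2 = 1, n_loci = 30)
  fx_b <- tmp_sam_fixture(sim_truth(prof_b, grid_solution(1, 20), seed = 43,
                                    depth_noise = "fixed"))
  all_b <- cellline_scan(fx_b$sam, load_candidate_loci(fx_b$loci),
                         loh_keep_fraction = 0.05, seed = 7)
  expect_equal(nrow(all_b), 30L)
})

test_that("observation tables round-trip through TSV", {
  obs <- data.frame(chrom = "chr1", pos = c(1L, 2L), depth = c(30L, 40L),
                    minor_fraction = c(0.5, 0.25))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_observations(obs, path)
  expect_equal(read_observations(path), obs)
})
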