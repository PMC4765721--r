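# Shared generators for tests: everything is built in code at test time.

# A realistic informative tumour profile: balanced diploid, LOH, unbalanced
# gain, balanced tetraploid, 3+1 gain.
informative_states <- function() {
  rbind(c(1, 1), c(2, 0), c(2, 1), c(2, 2), c(3, 1))
}

informative_profile <- function(n_loci = 150L) {
  st <- informative_states()
  segment_profile(n1 = st[, 1], n2 = st[, 2], n_loci = n_loci)
}

# Small truth + SAM fixture in a temp dir; returns paths and the realised
# observations.
tmp_sam_fixture <- function(truth, dir = withr::local_tempdir(.local_envir =
                                                              parent.frame()),
                            ...) {
  sam <- file.path(dir, "fixture.sam")
  write_sam_fixture(truth, sam, ...)
}

# Monte-Carlo oracle for the folded expectation, independent of the
# enumeration in the package.
mc_folded_fraction <- function(p, d, n = 1e6, seed = 42) {
  set.seed(seed)
  x <- rbinom(n, d, p)
  v <- pmin(x, d - x) / d
  list(mean = mean(v), se = sd(v) / sqrt(n))
}
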