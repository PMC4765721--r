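Package: bafgrid
Title: Grid-Plot Exploration of Tumour Cellularity and Single-Copy Depth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for resolving conflicting tumour cellularity (purity) and
    single-copy sequencing-depth solutions from whole-genome sequencing.
    Extracts depth and minor (B-) allele fraction at germline-heterozygous
    loci from alignment files, smooths them along the genome with a running
    median or mean, renders a two-dimensional density image with pixel-exact
    geometry metadata, and superimposes the copy-number state lattice
    predicted by a candidate (cellularity, single-copy depth) solution,
    including the folded-binomial correction to expected minor-allele
    fractions at finite depth. A grid-search fit quantifies how well
    competing solutions explain the observed density, and a simulator
    generates locus observations and small SAM fixtures from a known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rsamtools,
    GenomicRanges,
    IRanges,
    png,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
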