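---
title: "Resolving cellularity and single-copy depth with copy-number grid plots"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving cellularity and single-copy depth with copy-number grid plots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bafgrid)
```

## The problem

Whole-genome sequencing of a tumour sample mixes reads from tumour cells
with reads from contaminating normal (diploid) cells. Two quantities tie
the observed read depths and allele fractions to the tumour's copy-number
states: the **cellularity** $C$ (the fraction of cells that are tumour)
and the **single-copy depth** $D$ (the depth contributed by one
chromosomal copy present in every cell — half the depth of a diploid
region in a pure sample). Estimating $(C, D)$ is only partially
identifiable: different tools routinely return conflicting solutions, and
genome-doubled interpretations of the same data can be near-equivalent.
`bafgrid` renders the data as a 2D density of depth versus minor-allele
fraction at germline-heterozygous loci, superimposes the lattice of
predictions implied by any candidate $(C, D)$, and scores candidates
numerically, so that a user can see *why* each solution was offered and
choose between them with biological knowledge in hand.

## The model

For a genomic region carrying $n_1$ copies of one parental allele and
$n_2$ of the other ($n_2 \le n_1$ by the minor-allele convention), each
normal cell contributes two copies and each tumour cell $n_1 + n_2$, so
the expected total depth is

$$\mathrm{depth} = D\,[\,2(1 - C) + (n_1 + n_2)\,C\,]$$

and the expected minor-allele fraction at a germline-heterozygous locus
is

$$f = \frac{1 + C(n_2 - 1)}{2 + C(n_1 + n_2 - 2)}.$$

With $n_2 \le n_1$, $f \in [0, 0.5]$: balanced states sit at 0.5 for
every $C$, and unbalanced states move monotonically from 0.5 (pure
normal) toward $n_2/(n_1+n_2)$ (pure tumour). The state $(0, 0)$ at
$C = 1$ is degenerate — a homozygous deletion in a pure sample yields no
reads and no fraction — and is omitted from grids with a message rather
than failing the whole lattice: its depth coordinate (0) is real, but
keeping every emitted node's invariants simple is worth more than one
unplottable point.

### The folding correction

The minor allele is chosen *after* observation: if sampling noise pushes
the true minor allele's fraction above 0.5 at a locus, the other allele
is recorded instead. The probability mass above 0.5 folds back below it,
so the recorded mean sits below the true fraction — most strongly at low
depth and near balance. Modelling the reads carrying the true minor
allele as $X \sim \mathrm{Binomial}(d, p)$, the expected recorded
fraction is

$$E\!\left[\frac{\min(X, d - X)}{d}\right],$$

which `folded_expected_fraction()` computes by exact enumeration over
$k = 0, \dots, d$. Two choices here were genuinely open:

* **Distribution.** The read-count distribution is not prescribed by the
  model; binomial sampling of reads is the canonical minimal choice, and
  the simulator uses the same mechanism so the correction is a tested
  prediction, not an assumption. No overdispersed (beta-binomial)
  variant is offered — the tool's purpose is to reveal off-lattice mass,
  not to model it.
* **Fractional depths.** Predicted depths are real-valued; the folding
  is evaluated at the depth rounded to the nearest integer trial count.
  Interpolating between adjacent integers changes the result by far less
  than one fraction-axis pixel at any realistic depth.

At perfect balance the folded expectation is $0.3770$ at depth 10,
$0.4373$ at depth 40, and $0.4874$ at depth 1000 — the deficit shrinks
monotonically with depth.

## Scanning alignments

`tumour_normal_scan()` counts bases at a supplied list of candidate
heterozygous sites in both samples (through Rsamtools), calls a site
heterozygous in the normal when depth $\ge$ 15 and the second-most
frequent base holds between 30% and 70% of reads, and records the
tumour's depth and minor fraction at those sites. The quality defaults —
mapping quality $\ge$ 30, base quality $\ge$ 20, duplicates and secondary
alignments excluded — are conventional and configurable; they are stated
rather than inferred, since no canonical values exist for this step. The
minor fraction is computed over the two alleles seen in the normal
(third-allele reads are ignored in the numerator and denominator), which
keeps observations on the same biallelic scale as the model; the
recorded depth is the full filtered depth, which is what the depth
equation predicts.

Chromosome-name dialects (`chr1` versus `1`) are never translated
silently: a wholesale mismatch raises an error naming both spellings,
because silent renaming hides genuine reference mismatches.

`cellline_scan()` handles the no-matched-normal case. In a pure cell
line, a site that has lost heterozygosity is indistinguishable at a
single locus from a germline-homozygous site, and the homozygous mass
would drown the informative loci on the plot. Loci with minor fraction
below `loh_threshold` (default 0.1) are therefore retained at rate
`loh_keep_fraction` (default 0.05) under a caller-supplied seed. Both
values are conventions, logged on use; the retained set is exactly
reproducible given the seed.

## Smoothing

Per-locus fractions at 40× are noisy (binomial standard deviation
$\approx 0.08$ at balance), so `running_smooth()` applies a running
median (default) or mean over `window` neighbouring loci, independently
per chromosome, in positional order. At chromosome ends the window
shrinks symmetrically; a window of 1 is the identity. Smoothing across
chromosome boundaries would average unrelated copy-number states, so it
is not done. The window trades noise against resolution: with few loci a
wide window spans several true states and blends them — with 1,000 loci,
window 51 visibly merges clusters that window 11 keeps apart (a tested
property) — so the window should shrink as the locus count does.

**Median versus mean.** The plot default is the median (robust to
outliers). For *fitting*, however, the package defaults to the mean: the
folded fraction distribution is left-skewed near balance, so its median
sits above its mean, while grid nodes predict the mean. Median-smoothed
fractions therefore sit systematically above the folded nodes and drag
the fitted cellularity down by one to two grid steps at low purity — an
effect we measured directly in parameter-recovery simulations (a
consistent $-0.02$ bias in $\hat C$ at $C \approx 0.35$ that vanishes
under mean smoothing). Both statistics are exposed everywhere.

## The density image and pixel geometry

`render_density()` bins smoothed observations into a 2D histogram —
depth on the x axis (default limits 0–100 reads), minor fraction on the
y axis (always $[0, 0.5]$, since observations are minor fractions by
construction) — optionally blurs it with a small separable Gaussian, and
rasterises it into the plot region of an 800×800 PNG with a 60-px margin
(all overridable). The geometry is written to a plain `key=value`
sidecar file next to the PNG, so the data→pixel affine mapping can be
reconstructed exactly by any later overlay; images supplied without a
sidecar are assigned the defaults with a warning. Total histogram mass
equals the number of in-range observations; out-of-range points are
dropped with a logged count, and an all-out-of-range input is an error
naming the limits.

`render_overlay()` places each non-degenerate grid node at
`pixel(predicted depth, folded fraction)` through the *same* mapping
functions, so a density generated at the nodes and an overlay at the same
solution coincide within one pixel (a tested invariant). Node labels
(total copy and $(n_1, n_2)$) are returned in the node table rather than
rasterised into the image. The interactive session is a deliberately
thin text-command loop over `render_overlay()` — two continuous controls
($C \in [0,1]$, $D \in (0, \mathrm{depth_{max}}/2]$, since a single copy
beyond half the depth axis is never useful), axis-range editing, and
export of the current pair — so every computation is library code and
the whole loop is drivable from a scripted connection in tests.

## Scoring and fitting

`fit_score()` quantifies "this solution explains the observed states":
each smoothed observation's distance to the nearest grid node is taken
in normalised coordinates — depth differences divided by `depth_scale`
(default $D/2$, half a copy of depth) and fraction differences by
`fraction_scale` (default 0.05) — so one distance unit means one
half-copy of depth or five points of fraction. The summary is a 5%
trimmed mean (robust to a small share of off-lattice, e.g. sub-clonal,
mass) together with `fraction_explained`, the share of observations
within distance 1 of some node, which surfaces off-lattice mass instead
of averaging it away.

`grid_search()` evaluates every candidate pair exhaustively and returns
the full ranked table with deterministic tie-breaks (lower $C$, then
lower $D$). Observations are first thinned deterministically (evenly
spaced in genome order) to at most `max_obs` (default 1000); since
neighbouring smoothed values share most of their window, thinning at
this density discards little information while bounding the search cost.
`fit_baf_grid()` wraps smoothing plus search into a classed fit with
`coef`, `summary`, `predict`, `residuals`, `plot` and `simulate`
methods. `summary()` deliberately reports near-tied solutions at roughly
halved or doubled depth: genome-doubling aliasing is a genuine property
of the inference problem — a purely balanced-diploid sample ties $(C, D)$
with the doubled-genome reading at $D/2$ exactly — and the ranked list
keeps both families rather than collapsing them. The score is a
comparison aid, not an estimator with a stated error.

## The simulator

`simulate_observations()` generates what the scanner would produce for a
known truth: per-locus total depth Poisson around the depth equation's
mean (Poisson is the minimal coverage model; a `fixed` mode exists for
exact tests), reads of one fixed phased allele binomial around the
phased fraction $p = (1 - C + C n_2)/(2(1-C) + C(n_1+n_2))$ —
algebraically the same quantity as the minor-fraction equation — and the
recorded fraction $\min(x, d - x)/d$. Folding therefore *emerges* from
the sampling, exactly as in real data, and is never injected.
`write_sam_fixture()` materialises the same draws as a small
coordinate-sorted SAM file (reads above the default quality filters,
optional low-quality extras to exercise them), so the full scan path is
testable end to end: the scanner recovers the simulated counts exactly.

What the simulator does **not** emulate: GC-content and mappability
biases, mapping artefacts, germline polyploid regions, overdispersed
allele counts, and sub-clonal (non-integer) states. Tests passing on
synthetic data therefore demonstrate the correctness of the machinery
and the internal consistency of the model — not robustness to those
real-data artefacts, for which no correction is attempted.

## Problem sizes and reproducibility

The package's own validation uses desk-scale analogues of realistic
experiments: parameter recovery runs 20 simulated samples with five
informative states — (1,1), (2,0), (2,1), (2,2), (3,1): balanced
diploid, LOH, unbalanced gain, balanced tetraploid and a 3+1 gain, the
mixture a real tumour typically shows — at 600 loci per segment,
cellularities drawn from $[0.3, 0.9]$ and single-copy depths from
$[8, 25]$, searched over $C \in [0.3, 0.95]$ by 0.01 and
$D \in [5, 40]$ by 0.5. Three thousand loci is the deliberate
desk-scale counterpart of the $\sim$80,000 a real 40× scan yields;
recovery at these conditions is within one grid step in at least 90% of
runs, with any remaining misses confined to the halved/doubled-depth
aliasing family. All randomness flows through explicit integer seeds,
and every fixture is generated in code at run time.

## Known limitations

* No GC, mappability or germline-polyploidy corrections (see above).
* The score treats all lattice nodes as available; it does not penalise
  biologically implausible state usage, so adjudication between aliased
  solutions remains the user's task.
* Candidate-locus discovery is out of scope: the scanner consumes a
  supplied site list and is not a genome-wide heterozygosity caller.
* Indels, CRAM reference management and multi-sample views are not
  handled.
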