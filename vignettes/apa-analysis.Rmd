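---
title: "Quantifying differential poly(A)-site usage with apashift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying differential poly(A)-site usage with apashift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apashift)
```

## The problem and the model

Genes with several cleavage/polyadenylation sites (PAS) can shift their
usage between conditions — alternative polyadenylation (APA). When the shift
favors an upstream (proximal) PAS, transcripts shorten and, because 3′-end
processing is coupled to termination, transcription can terminate
prematurely; for noncoding RNAs that overlap a downstream promoter this can
relieve transcriptional interference. `apashift` detects such shifts from
RNA-seq coverage anchored on a PAS peak track.

The estimator works on *segments*: per gene, the windows delimited by its
retained PAS, ordered 5′→3′ in transcription direction. Reads covering the
most proximal segment come from all isoforms that reach the first PAS,
reads covering the most distal segment only from the longest isoforms, so
the distal:proximal coverage ratio tracks distal PAS usage. The per-gene
APA score compares that ratio between conditions:

$$\mathrm{score} = \log_2\frac{(d/p)_{\text{test}}}{(d/p)_{\text{ref}}}$$

with $d$ and $p$ the replicate-averaged, size-factor-normalized mean depths
of the most distal and most proximal segments. Negative scores mean the
test condition increases proximal usage.

Significance comes from a per-gene binomial generalized linear model: per
replicate, the distal read count out of distal + proximal trials, with
condition as the only covariate (logit link). This deliberately makes the
evidence scale with read depth — the same usage change is more convincing
at 1,000 reads than at 20 — rather than testing the ratio alone. P-values
(two-sided Wald on the condition coefficient by default) are
Benjamini–Hochberg adjusted, and events are called at |score| > 1 with
FDR < 0.01, then classified `proximal` or `distal` by the score's sign.

### Assumptions

* Within a replicate, the distal/proximal proportion is free of library
  size, so raw within-replicate counts enter the GLM; between-replicate
  variation in *usage* beyond binomial sampling (usage overdispersion) is
  not modelled by the default `binomial` family. A `quasibinomial` option
  exists for data where replicate usage scatters more than binomially.
* The PAS peak track (typically from a 3′-end assay of the reference
  strain) is treated as a fixed, condition-independent catalogue of sites.
* Segment mean depth is a faithful measure of isoform mass; biases that
  differ *between segments but identically across samples* cancel in the
  ratio-of-ratios.

## Segmentation rules and their edge cases

Peaks are retained when `count >= 6` (strictly "more than five reads") and
`count >= 0.05 * gene total` (inclusive), the total being computed over all
of the gene's peaks before filtering. Retained peaks closer than 50 nt
(strict: exactly 50 nt does not merge) merge at the stronger peak's
position with counts summed. Merging is iterative, closest pair first;
equally close pairs resolve to the lower-coordinate pair and equal-count
pairs place the merged peak at the more distal (3′) position. These
tie-breaks make the output deterministic and order-independent, which the
test suite verifies against a brute-force oracle on random peak lists.

Filtering precedes merging by default, following the order in which the
rules are stated for the method; since two sub-threshold peaks could
survive as one merged peak under the opposite order, `segment_genes()`
exposes `order = "merge_first"` for sensitivity analysis.

Segments end at (and include) their delimiting PAS; segment 1 starts at the
annotated TSS; the region downstream of the distal PAS is not a segment
(the score only needs PAS-terminated windows). Genes with fewer than two
retained peaks are flagged ineligible. Coverage is summed per segment to a
mass, a mean depth (mass/length, used in the score because it is
length-free), and an integer pseudo-count `round(mass / read_length)`
(default read length 100 nt) used by the GLM, which needs integer trials.

## Numerical choices

* **Zeros.** When any of the four averaged depths entering the score is
  zero, 0.5 is added to all four (Haldane–Anscombe style) so the score
  stays finite; when all four are positive no pseudocount is applied, so
  closed-form identities (a true −2 gives exactly −2) hold exactly.
* **GLM fitting** uses `stats::glm` (iteratively reweighted least squares)
  with convergence tolerance 1e-8 and at most 50 iterations. Non-converged
  or separated fits (unbounded coefficient; detected via an exploding
  standard error) fall back to a Wald test on the pooled condition totals
  with a 0.5 continuity correction and carry `glm_flag = TRUE`; genes with
  no reads return a missing p-value.
* **Multiple testing** is Benjamini–Hochberg throughout (the usage test and
  the k-mer screen).
* **Control genes** for sequence comparisons are the `n` non-significant
  genes with |score| nearest zero (ties by gene id) — an equal-size
  near-null group. Rank-based selection replaces fixed numeric score
  windows, which are dataset-specific.
* **Overlap tests** between gene sets report the sample odds ratio
  (ad/bc on the 2×2 table) and a one-sided exact hypergeometric tail.

## Sequence analysis

Windows of 40 nt immediately upstream and downstream of each proximal
cleavage site are extracted 5′→3′ in transcription direction
(minus-strand windows reverse-complemented; the cleavage base itself
belongs to neither window, as cleavage occurs between nucleotides) and
reported in the RNA alphabet. Uridine composition is compared per window
between affected and control groups with a two-sided rank-sum test — robust
and free of pooling assumptions; a pooled-count chi-square option exists.
The motif screen enumerates exact k-mers (k = 4–7), counts windows
containing each, and tests one-sided enrichment in the affected group with
an exact hypergeometric test, BH-corrected over all k-mers observed. This
is a deliberately simple discriminative screen: it has no degenerate
(IUPAC) letters, so a degenerate motif surfaces as its strongest exact
constituents.

## What the generator emulates — and what it does not

`simulation_config()` defaults encode the study design the package targets:
genes with 2–4 PAS; two replicates per condition; gene totals
negative-binomial with dispersion 0.05 (mild biological overdispersion)
around `library_multiplier × 300` reads; usage shifts of two log2 odds
units injected in 10% of genes, 85% of them proximal; a 6-mer U-rich motif
(`UUGUUG`) embedded downstream of affected proximal PAS in 50% of affected
versus 5% of control genes; 500 3′-end reads per gene for the peak track;
5% of genes carry a decoy peak < 50 nt from the distal PAS to exercise
merging. Middle PAS of 3- and 4-site genes share a fixed 20% of usage so
the injected odds change acts purely on the proximal/distal pair, making
the generator's `true_score` exactly the estimand of the APA score.

Per replicate, the gene total is drawn negative-binomially and split
multinomially across segments by usage. Each segment count is therefore
marginally negative-binomial (thinning preserves the dispersion parameter)
while within-replicate usage given the total stays binomial — so the
binomial GLM is correctly specified under the simulated null, and its
type-I error can be meaningfully checked (the acceptance tests find it
within [0.03, 0.07] at α = 0.05 on 2,000 null genes).

Two idealizations matter when extrapolating to real data:

* **Segment counts are proportional to their own PAS usage**, not to the
  cumulative usage of all downstream sites as real RNA-seq coverage is.
  Real coverage attenuates the score (with two sites, the proximal segment
  carries all isoforms, so the observed ratio estimates distal usage rather
  than distal:proximal odds); recovery numbers from the generator are
  therefore upper bounds on real-data effect-size recovery, though
  direction and calibration are unaffected.
* **Coverage bedGraphs are piecewise-constant per segment** (count ×
  read-length / length). The pipeline consumes coverage, not reads, so
  read-level artifacts (edge effects, mappability, internal priming) are
  out of scope; quantification on the generated tracks round-trips to the
  simulated counts exactly.

Passing tests on this generator demonstrate correct arithmetic, calibrated
testing under the stated noise model, and end-to-end coordinate handling —
not robustness to annotation errors, peak-calling noise, or 3′-bias, which
real data add.

## Problem sizes used by the tests

The test-suite calibrations use 2,000 genes for the null and recovery
studies, 1,000 random peak lists for the segmentation oracle, 10,000
random p-vectors for the FDR oracle, 200 + 200 windows for motif recovery
with 100 null replications, and a 60-gene bundle for the genome-mirror
invariance check; these sizes give stable Monte-Carlo estimates for the
asserted bounds while keeping the default test run short.

## Known limitations

* Two-condition designs only; no covariates beyond condition.
* The PAS catalogue is external input; no de-novo peak calling or
  internal-priming filtering.
* Usage overdispersion across replicates is only available via
  `family = "quasibinomial"`; with the default binomial family, datasets
  with strong replicate scatter will be anticonservative.
* The feature annotation assigns one feature per proximal PAS from the
  gene's UTR/CDS intervals; intron-aware isoform structure is not modelled.

## A compact end-to-end run

```{r, eval = FALSE}
cfg <- run_config(output_dir = "apa_out",
                  simulate = list(n_genes = 100, frac_shifted = 0.2),
                  seed = 1)
out <- apa_run("all", cfg)
res <- read.delim(out$results)
table(res$class)
```
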