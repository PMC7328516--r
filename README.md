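# apashift

Differential poly(A)-site usage from segmented RNA-seq coverage.

Most eukaryotic genes carry several cleavage/polyadenylation sites (PAS), and
shifts between them — alternative polyadenylation (APA) — change transcript
length, stability, and, for noncoding RNAs, whether transcription terminates
prematurely. `apashift` quantifies such shifts between two conditions (for
example a wild-type strain and an RNA-polymerase-II slow mutant, or replete
versus starved cells) from two standard inputs: a 3′-end-sequencing peak
track that marks PAS positions with their read support, and per-sample
RNA-seq coverage.

It is aimed at transcriptomics analysts who have gene annotation (GFF3), PAS
peaks (BED6 with read counts), and coverage (bedGraph) or per-segment count
tables (TSV), and want per-gene APA calls with calibrated statistics.

## Method

1. **Segmentation.** Per gene, PAS peaks are kept when they carry more than
   five reads *and* at least 5% of the gene's total 3′-end reads; peaks
   closer than 50 nt are merged at the stronger peak's position (counts
   summed). The gene is then divided into ordered windows, each ending at a
   retained PAS; genes with at least two windows are eligible.
2. **Scoring.** Segment coverage is normalized with median-of-ratios size
   factors. With distal/proximal mean-depth ratios `r_c` per condition `c`,
   each gene's APA score is

   `score = log2( r_test / r_ref ) = log2[ (test/ref)_distal / (test/ref)_proximal ]`

   Negative scores mean the test condition shifts usage towards the
   proximal PAS.
3. **Testing.** Per replicate, the distal count out of distal + proximal is
   modelled with a binomial GLM (logit link) on condition; the condition
   coefficient's two-sided Wald p-value is Benjamini–Hochberg adjusted.
   Events are called at |score| > 1 and FDR < 0.01 and classified as
   `proximal` or `distal`.
4. **Annotation and sequence context.** Each event's proximal PAS is located
   within gene features (5′UTR/CDS/3′UTR/ncRNA); 40-nt windows flanking
   affected and matched unaffected proximal cleavage sites are compared by
   uridine composition (rank-sum) and a discriminative exact k-mer
   enrichment (hypergeometric, BH-corrected).

A synthetic-data generator (`simulate_bundle()`, `simulate_apa_counts()`)
produces complete input bundles with known ground truth for calibration and
power studies.

## Worked example

```r
library(apashift)

cfg <- simulation_config(n_genes = 200, frac_shifted = 0.2, seed = 42)
sim <- simulate_apa_counts(cfg)   # truth table + segment counts
fit <- apa_fit(sim$counts)
fit
#> Differential PAS usage fit: 200 eligible genes (0 skipped)
#>   thresholds: |APA score| > 1, FDR < 0.01 (binomial wald GLM)
#>   events: 34 proximal, 6 distal, 160 unchanged

head(coef(fit), 3)
#>      g0001      g0002      g0003
#>  0.0246043 -1.9775360 -1.7178496
```

200 simulated genes, 20% with an injected two-log2-unit usage shift (85% of
them proximal): the fit recovers 40 events, 34 proximal — `g0002`'s score of
−1.98 estimates its true injected score of −2, while `g0001` (a null gene)
sits at 0.02. `summary(fit)` lists the top events with their FDR and
`plot(fit)` draws the volcano of score against −log10 FDR.

The same analysis runs from files:

```sh
exec/apashift all --config config.yaml --seed 42
```

which chains simulate → segment → score → annotate → motifs, writing TSV
results and JSON run logs under the configured output directory.

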