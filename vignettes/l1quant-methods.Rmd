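---
title: "Quantifying promoter-driven LINE-1 expression in single cells: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying promoter-driven LINE-1 expression in single cells: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(l1quant)
```

## The problem

LINE-1 (L1) is the only autonomously active retrotransposon in the human
genome. Its internal 5'UTR promoter drives *active* transcription — the
expression that matters for retrotransposition and for L1's role in cancer
and aging — but the vast majority of L1 sequence reads in any RNA-seq
library are *passive*: L1 fragments co-transcribed inside host gene
introns and UTRs. Standard scRNA-seq quantifiers count both
indiscriminately. Because 5'-targeted single-cell chemistry reads the
exact transcription start site (TSS) of each captured molecule, reads
whose alignment starts at the first bases of the L1 consensus are, almost
by definition, evidence of promoter-driven initiation. `l1quant`
implements this idea end to end: composite reference construction,
TSS-anchored read filtering, per-cell UMI counting, coverage profiling,
and a depth-offset negative-binomial test for differential L1 expression.

## Composite reference

Young L1 copies are so similar that their reads multi-map and are
discarded by aligners. The fix is to hard-mask every annotated L1 locus in
the genome with `N` (`mask_intervals`, the semantics of
`bedtools maskfasta`) and append family consensus sequences as decoy
contigs (`append_decoys`). Repeat-derived reads then align uniquely to one
representative. Hard masking rather than lowercase soft-masking is
deliberate: the downstream aligner must not seed reads inside the masked
loci at all. Masking is idempotent, length-conserving, and overlapping
intervals are unioned; decoy names may not collide with genome contigs.

For mouse, where three families (Tf, Gf, A) are active, the 5'UTR is a
tandem array of ~212-bp promoter monomers rather than a single
downstream promoter. `find_monomer_copies` locates approximate monomer
copies by edit-distance matching (substitutions and indels) with greedy
left-to-right tiling; the default edit budget is 10% of the monomer
length, a value chosen once to tolerate the divergence typical between
monomer units while rejecting unrelated sequence. `scan_motif` scans for
degenerate IUPAC motifs such as the initiator (Inr) element that marks
the inferred TSS inside the monomer. The Inr consensus string is a
configuration value (default `"YYANWYY"`): published analyses cite the
motif from the core-promoter literature without printing it, so it must
remain user-settable rather than hard-coded.

## Chemistry-specific filters

A record counts as active L1 evidence only under the rule-set of the
library chemistry (`chemistry_policy`), with all thresholds exposed:

* **`human_5p_paired`** (100/150-bp paired-end 5' chemistry): proper pair
  (SAM flag 2); read 1 starts within the first 20 consensus bases, has at
  most 19 bases clipped at its read-5' end (the template-switch oligo and
  extra template-switching G's survive barcode trimming as a soft clip),
  no 3' clip, at most 2 mismatches, forward strand; read 2 unclipped,
  at most 2 mismatches, reverse strand; CB and UB present.
* **`fiveprime_window`** (v2 chemistry, 26-bp read 1 that carries only
  barcodes): the only aligned read cannot pin the TSS, so reads starting
  anywhere within the first 150 or 500 consensus bases are counted —
  unclipped, at most 2 mismatches, sense strand only.
* **`human_3p`** (3' chemistry): unclipped reads fully inside the final
  1 kb of the consensus but outside the terminal poly-A stretch. The
  poly-A exclusion length is auto-detected as the terminal run of A's
  (tolerating one interior non-A; `detect_polya_run`) because no fixed
  coordinate generalizes across consensus builds.
* **`mouse_5p_paired`**: as the human paired mode, except read 1 must
  start inside any promoter monomer interval (the mouse TSS is dispersed
  across the tandem repeat) and the read-1 clip bound is inclusive
  (≤ 20). The one-base asymmetry against the human bound ("fewer than
  20" vs "up to 20") is preserved on purpose; both are configurable.

Mismatches are `NM` minus inserted/deleted bases, since `NM` counts indel
bases but the filters speak of mismatches. Clips are reported in *read*
orientation (soft + hard), so the 5'-clip bound applies to the biological
read start regardless of alignment strand. Rules are evaluated in a fixed
documented order and every rejection carries the first failing rule as a
reason code, which makes filter tallies reproducible and auditable.
Records with indels that survive the clip and mismatch rules are kept;
strand is not enforced in `human_3p` by default (a flag enables it) —
both choices reflect that the published rule lists are silent on these
cases, and both are exposed for sensitivity analysis. Barcodes are
required on read 1 in paired modes (cellranger tags both mates
identically, so the choice is immaterial in practice).

## Counting, merging, coverage

`count_l1_umis` reduces passing records to distinct molecular barcodes
per cell barcode — set cardinality, so duplicate reads of one molecule
count once. `attach_totals` joins the counts onto the cell-called barcode
universe of the filtered expression matrix; cells without L1 evidence get
an explicit zero, which is required for an unbiased GLM (dropping them
would condition on detection). `merge_samples` reproduces the aggr
barcode-suffix convention (`BARCODE-i`), and `downsample_even` equalizes
depth across samples before merging by keeping each read pair of sample
*s* with probability `min(depth)/depth_s`, mates together, reproducibly
per seed. The per-sample depth statistic is supplied by the caller
(confidently-mapped reads per cell-called cell is the intended default),
mirroring the aggr notion of depth without re-deriving it from the BAM.
`coverage_profile` tallies per-position depth split by read role and
strand after mismatch/strand filtering, the diagnostic view in which a
TSS peak (read 1 at the first consensus bases, read 2 just downstream)
distinguishes genuine promoter activity from uniform passive background.

## The offset NB GLM

Per-cell L1 UMI counts are small (often 0–3) and detection scales with
cell depth, so rank tests on log-normalized expression are biased toward
deep cells. Instead the package models

$$U_{L1,i} \sim \mathrm{NB}(\mu_i, \theta), \qquad
\mu_i = \exp\!\big(\log U_{\mathrm{total},i} + a X_i + b\big),$$

with the coefficient on $\log U_{\mathrm{total}}$ fixed at 1 (an offset).
$\exp(a)$ is then the fold-change in the per-molecule L1 rate between
predictor levels and $\exp(b)$ the baseline rate;
$\mathrm{TPM}(x) = 10^6 \exp(a x + b)$ (`estimate_tpm`), so
$\mathrm{TPM}(1)/\mathrm{TPM}(0) = e^a$ exactly. `fit_nb_glm` alternates
IRLS for $(a, b)$ with profile-likelihood updates of $\theta$
(method-of-moments start, $\theta \in [10^{-4}, 10^6]$, the upper cap
being the Poisson-like regime) until the log-likelihood moves by less
than $10^{-8}$, with step-halving so the likelihood never decreases.
P-values come from the likelihood-ratio test between nested fits
(`lrt_pvalue`), each fit keeping its own $\theta$, which is the
analysis-of-deviance convention for NB models; Wald standard errors from
the observed information (at fixed $\theta$) are also reported. Perfect
separation (one level all zeros) caps the coefficient at $|a| \le 30$ and
raises a warning flag rather than diverging; an all-zero response is an
error. Zero-inflation is deliberately not modeled. In tests the fit is
cross-checked against an independent implementation of the same model
(`MASS::glm.nb` with an offset term) and against brute-force grid
maximization of the likelihood.

## The synthetic-data generator

`sim_config`/`simulate_reference`/`simulate_cells`/`simulate_alignments`
generate every input the pipeline needs at desk scale. The defaults are
the study conditions used throughout the tests: two groups of cells with
$a = \log 4$, $b = \log 10^{-4}$, $\theta = 0.5$, per-cell totals
$\mathrm{round}(10^{N(4,\,0.5^2)})$, a 6-kb consensus ending in a 30-bp
poly-A run, TSO soft-clips of 13–19 bases, read-1 start jitter over the
first 5 consensus bases (TSS micro-heterogeneity), 2% antisense noise and
a $10^{-3}$ per-base error rate. Active molecules yield proper
R1+/R2− pairs anchored at the TSS; passive molecules yield internal/3'
reads on either strand, downstream of the promoter region by
construction; in 3'-chemistry mode *both* classes yield reads near the
consensus 3' end — which is precisely the confound that makes 3'
chemistry unsuitable for L1 quantification, and the package's end-to-end
tests reproduce it (3' counts track active+passive molecules, 5' counts
track active only). Cell barcodes are unique 16-mers and molecular
barcodes unique 10-mers per cell, emulating cellranger-corrected tags; no
barcode-error or PCR-duplicate model is included, and quality strings are
constant because the pipeline never reads them. What passing tests show
is therefore correctness of the *quantification logic*, not robustness to
alignment artifacts, barcode collisions or chimeric reads, which real
cellranger output can contain.

The benchmark problem sizes, chosen once as realistic desk-scale
conditions: exact-recovery runs use 500 cells at baseline rate
$10^{-3}$ (≈50k reads, zero error so truth equality is well-defined);
GLM recovery uses 50 replicates of 2,000 cells; null calibration uses
1,000 likelihood-ratio replicates at 500 cells. `scripts/acceptance.R`
re-runs all of these from scratch under a caller-supplied seed.

## Numerical and design notes

* Internal coordinates are 1-based closed throughout (the
  IRanges/Biostrings convention); BED's 0-based half-open records are
  converted at the I/O boundary by rtracklayer, and SAM positions stay
  1-based. Window rules read "first 20 bases" as positions 1–20.
* Degenerate inputs: empty interval sets, empty decoy lists, cells with
  zero passing records, and zero-length filter inputs are all valid and
  produce empty-but-typed results; unknown contigs, interval/contig
  overflows, barcode-less records reaching the counter, and non-nested
  LRT model pairs are hard errors.
* `find_monomer_copies` ties are broken left-to-right (greedy): with
  equal-quality overlapping candidates the 5'-most wins, which matches
  how a tandem promoter array is read.
* Downsampling, simulation and the totals-matrix writer take explicit
  seeds; a run is reproducible bit-for-bit given the seed.

## Limitations

The tool quantifies consensus-level, promoter-anchored expression: it
does not attribute reads to individual genomic loci (that is the job of
an EM multi-mapper such as the external tool whose inputs
`headcrop_fastq`/`shorten_bed` prepare), does not error-correct UMIs
(corrected tags are assumed), and does not model zero inflation or
multi-factor designs in the GLM. The synthetic generator validates logic,
not aligner behavior; conclusions about real data still depend on the
upstream aligner having been run against a properly masked composite
reference.
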