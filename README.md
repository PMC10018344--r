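# l1quant

Promoter-anchored quantification of LINE-1 retrotransposon expression
from 5'-targeted single-cell RNA-seq.

Most LINE-1 (L1) sequence in any RNA-seq library is *passive* — L1
fragments co-transcribed inside host gene transcripts — while the
biologically meaningful signal is *active* transcription initiated at the
L1 internal promoter. Because 5' single-cell chemistry captures the exact
transcription start site of each molecule, reads whose alignment begins
within the first bases of an L1 consensus sequence are direct evidence of
promoter-driven expression. `l1quant` is for researchers studying
transposable-element activity in cancer, aging or development who have
cellranger-style 5' scRNA-seq alignments and want per-cell active-L1 UMI
counts with a depth-aware differential test.

The package covers the full path:

* **Composite reference**: hard-mask annotated L1 loci in a genome and
  append family consensus decoy contigs, so repeat reads map uniquely to
  one representative (`mask_intervals`, `append_decoys`,
  `build_composite_reference`); locate mouse promoter-monomer tandem
  repeats and initiator motifs (`find_monomer_copies`, `scan_motif`).
* **Chemistry-specific filters**: four auditable rule-sets
  (`chemistry_policy`, `filter_alignments`) for paired human 5' data
  (TSS window, TSO soft-clip allowance, mismatch and strand rules),
  barcode-only-read-1 5' data (150/500-base windows), 3' data (final
  kilobase minus the poly-A stretch) and mouse 5' data (monomer-anchored
  read 1). Every rejected read carries a reason code.
* **Per-cell counting**: distinct molecular barcodes per cell barcode
  (`count_l1_umis`), totals attachment with explicit zeros
  (`attach_totals`), aggr-style merging and depth equalization
  (`merge_samples`, `downsample_even`), consensus coverage profiles
  (`coverage_profile`).
* **Inference**: a negative-binomial GLM with log link and a fixed
  unit-coefficient offset on log total UMIs,

  $$U_{L1} \sim \mathrm{NB}\big(\exp(\log U_{\mathrm{total}} + aX + b),\; \theta\big),$$

  so `exp(a)` is the fold-change in per-molecule L1 rate and
  `TPM = 1e6 * exp(aX + b)` (`fit_nb_glm`, `lrt_pvalue`, `estimate_tpm`,
  `l1_glm`).
* **Pseudobulk prep** for locus-level EM analysis: read-1 head-cropping
  and 5'-window annotation shortening (`headcrop_fastq`, `shorten_bed`).
* **A synthetic-data generator** (`sim_config`, `simulate_dataset`) that
  emulates cellranger-tagged alignments with active, passive and
  antisense read populations plus per-cell NB-distributed truth counts,
  so the entire pipeline is testable without any sequencing data.

## Worked example

Simulate a two-group 5' experiment (200 cells, 4-fold true difference),
filter, count and test:

```r
library(l1quant)

cfg    <- sim_config(seed = 42, n_cells_per_group = 100, baseline_b = log(1e-3))
refsim <- simulate_reference(cfg)
truth  <- simulate_cells(cfg)
sim    <- simulate_alignments(truth, refsim, cfg)

policy <- chemistry_policy("human_5p_paired", "L1HS", consensus = refsim$consensus)
filt   <- filter_alignments(sim$records, policy)
filt$reason_tally[filt$reason_tally > 0]
#>                      ok r1_start_outside_window        r1_3clip_present
#>                   22911                    4015                     493
#>     too_many_mismatches
#>                       5

counts <- attach_totals(count_l1_umis(filt$evidence),
                        data.frame(barcode = truth$barcode,
                                   u_total = truth$u_total))
counts$group <- truth$group[match(counts$barcode, truth$barcode)]
l1_glm(counts, "group")$summary
#>   predictor coef    se fold_change  p_value tpm_at_0 tpm_at_1
#> 1     group 1.53 0.212         4.6 4.24e-11     1054     4844
```

22,911 read pairs pass the TSS-anchored filter (the 4,015
`r1_start_outside_window` rejections are the simulated passive/internal
reads, the `r1_3clip_present` ones are antisense noise). The GLM
estimates a 4.6-fold difference in per-molecule L1 rate between the
groups (truth: 4-fold, within one standard error on 200 cells), with a
likelihood-ratio p of 4×10⁻¹¹ and model-based TPM at each predictor
level.

A thin command-line front end over the same functions is installed at
`inst/cli/l1quant.R` (`build-ref`, `quantify`, `coverage`, `glm`,
`headcrop`, `shorten-bed`, `simulate`).

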