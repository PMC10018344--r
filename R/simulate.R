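# Synthetic-data generator: toy composite references, per-cell truth
# counts drawn from the forward-run offset NB model, and cellranger-style
# tagged alignments with active (TSS-anchored, TSO-soft-clipped, proper
# R1+/R2- pairs), passive (internal/3', either strand) and antisense
# read populations. The generator is first-class: end-to-end tests use
# its truth tables as the oracle for the whole pipeline.

#' Simulation configuration
#'
#' Bundles every knob of the generator. Defaults describe a small but
#' realistic 5' experiment: two groups of cells whose LINE-1 rate
#' differs `exp(effect_a)`-fold, per-cell depths log-normal around 10^4
#' UMIs, NB dispersion `theta = 0.5`, a 6-kb consensus ending in a 30-bp
#' poly-A run, TSO soft-clips of 13-19 bases and read-1 starts within
#' the first `tss_jitter = 5` consensus bases.
#'
#' @param seed Integer seed; all generator randomness derives from it.
#' @param n_cells_per_group Cells per group (two groups, X = 0/1).
#' @param effect_a Group log fold-change (default `log(4)`).
#' @param baseline_b Baseline log per-molecule LINE-1 rate
#'   (default `log(1e-4)`).
#' @param theta NB dispersion of the per-cell counts (default 0.5).
#' @param total_log10_mean,total_log10_sd Per-cell total UMIs are
#'   `round(10^N(mean, sd))`, floored at 1 (defaults 4 and 0.5).
#' @param chemistry One of `"human_5p_paired"`, `"fiveprime_window"`,
#'   `"human_3p"`, `"mouse_5p_paired"`.
#' @param passive_rate Expected passive LINE-1 molecules per total UMI
#'   (per cell: `Poisson(u_total * passive_rate)`); 0 for none.
#' @param antisense_frac Fraction of active read pairs emitted with
#'   flipped strand (noise the filters must reject).
#' @param error_rate Per-base substitution rate reflected in NM.
#' @param reads_per_molecule_mean Mean read (pairs) per molecule
#'   (`1 + Poisson(mean - 1)`).
#' @param tso_clip_range Read-1 5' soft-clip lengths (TSO remnant).
#' @param r1_len,r2_len Read lengths.
#' @param consensus_len Decoy consensus length (incl. poly-A tail).
#' @param polya_len Terminal poly-A run length.
#' @param tss_jitter Active read-1 starts are uniform on
#'   `1..tss_jitter`.
#' @param monomer_n,monomer_len Mouse mode: number and length of
#'   promoter monomer copies prepended to the consensus.
#' @param barcode_len,umi_len Cell/molecular barcode lengths.
#' @return A `SimulationConfig` list.
#' @export
sim_config <- function(seed = 1L,
                       n_cells_per_group = 250L,
                       effect_a = log(4),
                       baseline_b = log(1e-4),
                       theta = 0.5,
                       total_log10_mean = 4,
                       total_log10_sd = 0.5,
                       chemistry = "human_5p_paired",
                       passive_rate = 5e-4,
                       antisense_frac = 0.02,
                       error_rate = 0.001,
                       reads_per_molecule_mean = 2,
                       tso_clip_range = 13:19,
                       r1_len = 150L, r2_len = 90L,
                       consensus_len = 6000L,
                       polya_len = 30L,
                       tss_jitter = 5L,
                       monomer_n = 3L, monomer_len = 212L,
                       barcode_len = 16L, umi_len = 10L) {
  chemistry <- match.arg(chemistry, POLICY_MODES)
  stopifnot(consensus_len >= 1000L, passive_rate >= 0, antisense_frac >= 0,
            antisense_frac <= 1, error_rate >= 0, error_rate < 1,
            reads_per_molecule_mean >= 1, tss_jitter >= 1L)
  structure(as.list(environment()), class = "SimulationConfig")
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

unique_barcodes <- function(n, len) {
  out <- unique(random_dna(n, len))
  while (length(out) < n)
    out <- unique(c(out, random_dna(n - length(out), len)))
  out
}

#' Simulate a toy composite reference
#'
#' Emits a two-contig toy genome carrying embedded truncated LINE-1
#' fragments (passive-source loci, annotated), plus a decoy consensus
#' ending in a poly-A run. In mouse mode the consensus starts with
#' `monomer_n` copies of a promoter monomer. Deterministic per seed.
#'
#' @param config A [sim_config()].
#' @return A list: `reference` (`CompositeReference`), `annotation`
#'   (`GRanges` of the embedded fragments), `consensus_name`,
#'   `consensus` (character), `monomer` (character, mouse) and
#'   `monomers` (`GRanges`, mouse).
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  withr::with_seed(config$seed, {
    mouse <- config$chemistry == "mouse_5p_paired"
    cname <- if (mouse) "L1MdTf_I" else "L1HS"
    polya <- strrep("A", config$polya_len)
    monomer <- NULL; monomers <- GenomicRanges::GRanges()
    if (mouse) {
      monomer <- random_dna(1, config$monomer_len)
      head_len <- config$monomer_n * config$monomer_len
      body <- random_dna(1, config$consensus_len - head_len - config$polya_len)
      consensus <- paste0(strrep(monomer, config$monomer_n), body, polya)
      monomers <- GenomicRanges::GRanges(
        cname, IRanges::IRanges(
          start = (seq_len(config$monomer_n) - 1L) * config$monomer_len + 1L,
          width = config$monomer_len), strand = "+")
    } else {
      consensus <- paste0(
        random_dna(1, config$consensus_len - config$polya_len), polya)
    }
    # genome contigs with embedded truncated (3'-half) fragments
    glen <- 20000L
    frag_w <- 800L
    genome <- stats::setNames(random_dna(2, glen), c("chrA", "chrB"))
    frag <- substr(consensus, config$consensus_len - config$polya_len - frag_w + 1L,
                   config$consensus_len - config$polya_len)
    at <- c(chrA = 5001L, chrB = 12001L)
    for (ctg in names(at))
      substr(genome[[ctg]], at[[ctg]], at[[ctg]] + frag_w - 1L) <- frag
    annotation <- GenomicRanges::GRanges(
      names(at), IRanges::IRanges(at, width = frag_w), strand = "+")
    names(annotation) <- paste0("L1_frag_", names(at))
    ref <- append_decoys(
      Biostrings::DNAStringSet(genome),
      Biostrings::DNAStringSet(stats::setNames(consensus, cname)))
    list(reference = ref, annotation = annotation, consensus_name = cname,
         consensus = consensus, monomer = monomer, monomers = monomers)
  })
}

#' Simulate per-cell truth counts
#'
#' Runs the offset NB model forward: totals `u_total ~ round(10^N)`,
#' active LINE-1 molecules
#' `u_l1 ~ NB(mu = u_total * exp(a X + b), theta)`, passive molecules
#' `~ Poisson(u_total * passive_rate)` independently.
#'
#' @param config A [sim_config()].
#' @return A `TruthTable` data.frame: `barcode`, `group` (0/1),
#'   `u_total`, `u_l1` (active molecules), `n_passive`.
#' @export
simulate_cells <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  withr::with_seed(config$seed + 1L, {
    n <- 2L * config$n_cells_per_group
    group <- rep(0:1, each = config$n_cells_per_group)
    u_total <- pmax(1L, as.integer(round(
      10^stats::rnorm(n, config$total_log10_mean, config$total_log10_sd))))
    mu <- u_total * exp(config$effect_a * group + config$baseline_b)
    u_l1 <- as.integer(stats::rnbinom(n, size = config$theta, mu = mu))
    n_passive <- as.integer(stats::rpois(n, u_total * config$passive_rate))
    out <- data.frame(barcode = unique_barcodes(n, config$barcode_len),
                      group = group, u_total = u_total, u_l1 = u_l1,
                      n_passive = n_passive, stringsAsFactors = FALSE)
    class(out) <- c("TruthTable", "data.frame")
    out
  })
}

mutate_bases <- function(seqs, n_errors) {
  idx <- which(n_errors > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in idx) {
    s <- strsplit(seqs[i], "")[[1]]
    at <- sample(length(s), min(n_errors[i], length(s)))
    s[at] <- vapply(s[at], function(b) sample(setdiff(bases, b), 1),
                    character(1))
    seqs[i] <- paste(s, collapse = "")
  }
  seqs
}

revcomp <- function(seqs) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs)))
}

#' Simulate tagged alignments from a truth table
#'
#' Emits one SAM-ready record table. Active molecules produce
#' chemistry-appropriate reads anchored at the consensus 5' end (proper
#' R1+/R2- pairs with a TSO soft-clip on read 1 for the paired
#' chemistries; sense single reads for the window chemistry); in 3'
#' chemistry both active and passive molecules produce reads near the
#' consensus 3' end, which is exactly why that chemistry cannot separate
#' promoter-driven from passive LINE-1 expression. Passive molecules in
#' 5' chemistries produce internal/3' reads on either strand. A fraction
#' of active reads is flipped to antisense as noise. Per-base errors are
#' reflected in both SEQ and NM. Every read carries CB/UB/NM tags.
#'
#' @param truth A [simulate_cells()] table.
#' @param refsim A [simulate_reference()] result from the same config.
#' @param config The shared [sim_config()].
#' @return A list: `records` (an `l1_alignments` data.frame with extra
#'   SAM columns `seq`, `qual`, `class`, `role`), `contig_lengths`
#'   (named, for the SAM header), `truth`.
#' @export
simulate_alignments <- function(truth, refsim, config) {
  stopifnot(inherits(config, "SimulationConfig"),
            inherits(truth, "TruthTable"))
  L <- config$consensus_len
  cname <- refsim$consensus_name
  if (nchar(refsim$consensus) != L)
    stop("truth/reference mismatch: consensus length differs from config")
  cons <- refsim$consensus
  withr::with_seed(config$seed + 2L, {
    mol <- data.frame(
      cb = c(rep(truth$barcode, truth$u_l1), rep(truth$barcode, truth$n_passive)),
      class = rep(c("active", "passive"), c(sum(truth$u_l1), sum(truth$n_passive))),
      stringsAsFactors = FALSE)
    n_mol <- nrow(mol)
    if (n_mol == 0L)
      return(list(records = empty_sim_records(), contig_lengths = contig_lens(refsim),
                  truth = truth))
    # molecular barcodes: distinct per molecule within a cell
    mol$ub <- random_dna(n_mol, config$umi_len)
    repeat {
      dup <- duplicated(paste0(mol$cb, "\r", mol$ub))
      if (!any(dup)) break
      mol$ub[dup] <- random_dna(sum(dup), config$umi_len)
    }
    n_reads <- 1L + stats::rpois(n_mol, config$reads_per_molecule_mean - 1)
    ridx <- rep(seq_len(n_mol), n_reads)
    rd <- mol[ridx, , drop = FALSE]
    n <- nrow(rd)
    rd$qname <- sprintf("sim%08d", seq_len(n))
    active <- rd$class == "active"

    take <- function(start, width) substr(rep(cons, length(start)), start,
                                          start + width - 1L)
    err <- function(width) stats::rbinom(length(width), width, config$error_rate)

    if (config$chemistry %in% c("human_5p_paired", "mouse_5p_paired")) {
      # ---- read 1 ----
      clip <- sample(config$tso_clip_range, n, replace = TRUE)
      m1 <- config$r1_len - clip
      pos1 <- integer(n)
      if (config$chemistry == "human_5p_paired") {
        pos1[active] <- sample(config$tss_jitter, sum(active), replace = TRUE)
      } else {
        mono <- refsim$monomers
        pick <- sample(length(mono), sum(active), replace = TRUE)
        pos1[active] <- BiocGenerics::start(mono)[pick] +
          sample(0:20, sum(active), replace = TRUE)
      }
      # passive reads are internal/3': downstream of the promoter region
      body_lo <- if (config$chemistry == "mouse_5p_paired")
        max(BiocGenerics::end(refsim$monomers)) + 64L else 500L
      pos1[!active] <- sample(body_lo:(L - 600L), sum(!active), replace = TRUE)
      cigar1 <- ifelse(active, sprintf("%dS%dM", clip, m1),
                       sprintf("%dM", config$r1_len))
      m1 <- ifelse(active, m1, config$r1_len)
      nm1 <- err(m1)
      seq1core <- mutate_bases(take(pos1, m1), nm1)
      # the soft-clipped head stands in for the TSO remnant / extra G's
      seq1 <- ifelse(active, paste0(strrep("G", clip), seq1core), seq1core)
      # ---- read 2 ----
      gap <- sample(0:100, n, replace = TRUE)
      pos2 <- pos1 + m1 + gap
      pos2 <- pmin(pos2, L - config$r2_len + 1L)
      nm2 <- err(rep(config$r2_len, n))
      seq2 <- revcomp(mutate_bases(take(pos2, config$r2_len), nm2))
      cigar2 <- sprintf("%dM", config$r2_len)
      flip <- active & stats::runif(n) < config$antisense_frac
      # passive pairs: half in sense orientation, half antisense
      pflip <- !active & stats::runif(n) < 0.5
      rev1 <- flip | pflip
      flag1 <- ifelse(rev1, 83L, 99L)
      flag2 <- ifelse(rev1, 163L, 147L)
      rd$class[flip] <- "antisense"
      out <- rbind(
        sim_rec(rd, flag1, cname, pos1, cigar1, nm1, seq1, "r1"),
        sim_rec(rd, flag2, cname, pos2, cigar2, nm2, seq2, "r2"))
      out$tlen <- 0L
      i1 <- seq_len(n); i2 <- n + seq_len(n)
      out$rnext <- "="
      out$pnext[i1] <- out$pos[i2]; out$pnext[i2] <- out$pos[i1]
    } else if (config$chemistry == "fiveprime_window") {
      pos <- integer(n)
      pos[active] <- sample(1:100, sum(active), replace = TRUE)
      pos[!active] <- sample(600:(L - 200L), sum(!active), replace = TRUE)
      nm <- err(rep(config$r2_len, n))
      seqs <- revcomp(mutate_bases(take(pos, config$r2_len), nm))
      flip <- stats::runif(n) < config$antisense_frac
      flag <- ifelse(flip, 0L, 16L)     # sense read 2 aligns reverse
      rd$class[flip & active] <- "antisense"
      out <- sim_rec(rd, flag, cname, pos, sprintf("%dM", config$r2_len),
                     nm, seqs, "r2")
    } else { # human_3p: both classes yield reads near the 3' end
      pos <- sample((L - 800L):(L - 200L - config$r2_len), n, replace = TRUE)
      nm <- err(rep(config$r2_len, n))
      seqs <- mutate_bases(take(pos, config$r2_len), nm)
      out <- sim_rec(rd, 0L, cname, pos, sprintf("%dM", config$r2_len),
                     nm, seqs, "r2")
    }
    out$qual <- strrep("F", nchar(out$seq))
    rownames(out) <- NULL
    class(out) <- c("l1_alignments", "data.frame")
    list(records = out, contig_lengths = contig_lens(refsim), truth = truth)
  })
}

contig_lens <- function(refsim) {
  s <- composite_sequences(refsim$reference)
  stats::setNames(lengths(s), names(s))
}

sim_rec <- function(rd, flag, rname, pos, cigar, nm, seqs, role) {
  data.frame(qname = rd$qname, flag = as.integer(flag), rname = rname,
             pos = as.integer(pos), cigar = cigar, nm = as.integer(nm),
             cb = rd$cb, ub = rd$ub, seq = seqs, qual = "",
             class = rd$class, role = role,
             rnext = "*", pnext = 0L, tlen = 0L,
             stringsAsFactors = FALSE)
}

empty_sim_records <- function() {
  out <- alignment_record(character(0), integer(0), character(0),
                          integer(0), character(0))
  out$seq <- character(0); out$qual <- character(0)
  out$class <- character(0); out$role <- character(0)
  out$rnext <- character(0); out$pnext <- integer(0); out$tlen <- integer(0)
  out
}

#' Write simulated records as SAM
#'
#' @param sim A [simulate_alignments()] result (or a compatible record
#'   data.frame plus `contig_lengths`).
#' @param path Output `.sam` path.
#' @param contig_lengths Named contig lengths for the header (taken from
#'   `sim` when it is a simulation result).
#' @return `path`, invisibly.
#' @export
write_sam <- function(sim, path, contig_lengths = NULL) {
  if (is.list(sim) && !is.data.frame(sim)) {
    contig_lengths <- sim$contig_lengths
    records <- sim$records
  } else records <- sim
  stopifnot(!is.null(contig_lengths))
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contig_lengths),
                   as.integer(contig_lengths)))
  body <- sprintf("%s\t%d\t%s\t%d\t255\t%s\t%s\t%d\t%d\t%s\t%s\tNM:i:%d\tCB:Z:%s\tUB:Z:%s",
                  records$qname, records$flag, records$rname, records$pos,
                  records$cigar, records$rnext, records$pnext, records$tlen,
                  records$seq, records$qual, records$nm, records$cb,
                  records$ub)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write simulated raw read-1 FASTQ
#'
#' Reconstructs the raw read 1 of the paired 5' chemistry: 16-base cell
#' barcode + molecular barcode + the aligned read-1 sequence (whose
#' soft-clipped head is the TSO remnant), so the first 46 bases are
#' non-transcript and `HEADCROP:46`-style trimming applies.
#'
#' @param sim A [simulate_alignments()] result.
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_fastq_r1 <- function(sim, path) {
  r1 <- sim$records[sim$records$role == "r1", , drop = FALSE]
  seqs <- paste0(r1$cb, r1$ub, r1$seq)
  lines <- as.vector(rbind(paste0("@", r1$qname), seqs, "+",
                           strrep("F", nchar(seqs))))
  writeLines(lines, path)
  invisible(path)
}

#' Simulate a complete dataset on disk
#'
#' One-stop driver: reference FASTA, tagged SAM, totals matrix directory
#' and truth TSV under `dir`, all derived from `config$seed`.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created).
#' @return Invisibly, a list with the in-memory objects (`refsim`,
#'   `truth`, `sim`) and file `paths`.
#' @export
simulate_dataset <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  refsim <- simulate_reference(config)
  truth <- simulate_cells(config)
  sim <- simulate_alignments(truth, refsim, config)
  paths <- list(
    fasta = file.path(dir, "composite.fa"),
    sam = file.path(dir, "alignments.sam"),
    truth = file.path(dir, "truth.tsv"),
    totals = file.path(dir, "totals_mtx"))
  write_composite(refsim$reference, paths$fasta)
  write_sam(sim, paths$sam)
  utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_totals_mtx(truth[, c("barcode", "u_total")], paths$totals,
                   seed = config$seed + 3L)
  invisible(list(refsim = refsim, truth = truth, sim = sim, paths = paths))
}
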