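# Composite-reference construction: mask annotated LINE-1 loci in a genome
# assembly, then append family consensus sequences as decoy contigs so that
# repeat-derived reads map uniquely to one representative.

#' Read a genome or consensus FASTA into a DNAStringSet
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] that trims FASTA
#' descriptions down to the first whitespace-delimited token, the contig
#' name cellranger/STAR will use.
#'
#' @param path Path to a FASTA file (plain or gzip).
#' @return A [Biostrings::DNAStringSet] named by contig.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(x)))
    stop("duplicate contig names in ", path)
  if (any(nchar(names(x)) == 0L) || any(lengths(x) == 0L))
    stop("empty contig name or sequence in ", path)
  x
}

#' Read a BED file of intervals to mask
#'
#' BED intervals are 0-based half-open on disk; the returned
#' [GenomicRanges::GRanges] uses the usual R 1-based closed convention
#' (rtracklayer performs the shift).
#'
#' @param path Path to a BED file (3-6 columns).
#' @return A `GRanges` of the records.
#' @export
read_mask_bed <- function(path) {
  rtracklayer::import(path, format = "BED")
}

#' Mask intervals of an assembly with 'N'
#'
#' Replaces every base covered by `intervals` with `N`, mirroring
#' `bedtools maskfasta` hard-masking. Overlapping intervals are unioned;
#' all uncovered bases and all contig lengths are preserved exactly.
#' Hard masking (rather than lowercase soft masking) is used because the
#' downstream aligner must not seed reads inside the masked loci.
#'
#' @param assembly A named [Biostrings::DNAStringSet].
#' @param intervals A [GenomicRanges::GRanges] (or anything coercible) of
#'   regions to mask; seqnames must name contigs of `assembly` and every
#'   interval must lie within its contig.
#' @return The masked `DNAStringSet`, same names and lengths, with an
#'   attribute `mask_stats` recording the number of input intervals and of
#'   distinct masked positions.
#' @examples
#' asm <- Biostrings::DNAStringSet(c(chrT = strrep("ACGT", 25)))
#' gr <- GenomicRanges::GRanges("chrT", IRanges::IRanges(11, 20))
#' masked <- mask_intervals(asm, gr)
#' @export
mask_intervals <- function(assembly, intervals) {
  stopifnot(methods::is(assembly, "DNAStringSet"))
  intervals <- methods::as(intervals, "GRanges")
  ctg <- as.character(GenomicRanges::seqnames(intervals))
  unknown <- setdiff(unique(ctg), names(assembly))
  if (length(unknown))
    stop("mask interval on unknown contig(s): ", paste(unknown, collapse = ", "))
  if (any(IRanges::width(intervals) < 1L))
    stop("mask interval with start >= end")
  lens <- stats::setNames(BiocGenerics::width(assembly), names(assembly))[ctg]
  bad <- IRanges::end(intervals) > lens | IRanges::start(intervals) < 1L
  if (any(bad))
    stop("mask interval outside its contig: ",
         paste(ctg[bad], IRanges::start(intervals)[bad], sep = ":", collapse = ", "))

  at <- lapply(names(assembly), function(nm) {
    IRanges::reduce(IRanges::ranges(intervals[ctg == nm]))
  })
  value <- lapply(at, function(r) strrep("N", IRanges::width(r)))
  out <- Biostrings::replaceAt(assembly, methods::as(at, "IRangesList"), value)
  names(at) <- names(assembly)
  attr(out, "mask_stats") <- list(
    n_intervals = length(intervals),
    n_masked_positions = sum(vapply(at, function(r) sum(IRanges::width(r)), 0))
  )
  out
}

#' Parse the family label from Dfam-style consensus record names
#'
#' Dfam FASTA headers look like `L1HS#LINE/L1`; the family is the token
#' before the first `#` (the whole name when no `#` is present).
#'
#' @param names Character vector of record names.
#' @return Character vector of family labels.
#' @export
decoy_family <- function(names) sub("#.*$", "", names)

#' Append consensus decoy contigs to a masked assembly
#'
#' Builds the composite reference: genome contigs first (order preserved),
#' then the decoys in the given order. Decoy names must not collide with
#' genome contigs or each other. Families listed in `exclude_family` are
#' dropped (used e.g. to exclude the non-expressed mouse subfamilies).
#'
#' @param masked A masked genome `DNAStringSet` (from [mask_intervals()]).
#' @param decoys A `DNAStringSet` of consensus sequences.
#' @param exclude_family Character vector of family labels to drop.
#' @return An object of class `CompositeReference`: a list with elements
#'   `genome`, `decoys` and `provenance`.
#' @export
append_decoys <- function(masked, decoys, exclude_family = character()) {
  stopifnot(methods::is(masked, "DNAStringSet"), methods::is(decoys, "DNAStringSet"))
  keep <- !(decoy_family(names(decoys)) %in% exclude_family)
  decoys <- decoys[keep]
  if (anyDuplicated(names(decoys)))
    stop("duplicate decoy names: ",
         paste(unique(names(decoys)[duplicated(names(decoys))]), collapse = ", "))
  clash <- intersect(names(decoys), names(masked))
  if (length(clash))
    stop("decoy name collides with genome contig: ", paste(clash, collapse = ", "))
  if (any(lengths(decoys) == 0L))
    stop("empty decoy sequence")
  ms <- attr(masked, "mask_stats")
  structure(list(
    genome = masked,
    decoys = decoys,
    provenance = list(
      n_genome_contigs = length(masked),
      genome_length = sum(lengths(masked)),
      n_decoys = length(decoys),
      decoy_length = sum(lengths(decoys)),
      mask_intervals = if (is.null(ms)) NA_integer_ else ms$n_intervals,
      masked_positions = if (is.null(ms)) NA_integer_ else ms$n_masked_positions,
      excluded_families = exclude_family
    )
  ), class = "CompositeReference")
}

#' Flatten a CompositeReference to a single DNAStringSet
#' @param ref A `CompositeReference`.
#' @return `DNAStringSet` of genome contigs followed by decoys.
#' @export
composite_sequences <- function(ref) {
  stopifnot(inherits(ref, "CompositeReference"))
  c(ref$genome, ref$decoys)
}

#' @export
print.CompositeReference <- function(x, ...) {
  p <- x$provenance
  cat("CompositeReference:", p$n_genome_contigs, "genome contig(s) (",
      p$genome_length, "bp ) +", p$n_decoys, "decoy(s) (", p$decoy_length, "bp )\n")
  cat("  masked positions:", p$masked_positions, "\n")
  invisible(x)
}

#' Write a composite reference and its provenance sidecar
#'
#' @param ref A `CompositeReference`.
#' @param path Output FASTA path; a plain-text sidecar `<path>.provenance.txt`
#'   is written next to it.
#' @return `path`, invisibly.
#' @export
write_composite <- function(ref, path) {
  Biostrings::writeXStringSet(composite_sequences(ref), path)
  p <- ref$provenance
  side <- paste0(path, ".provenance.txt")
  writeLines(c(
    paste("genome_contigs", p$n_genome_contigs),
    paste("genome_length", p$genome_length),
    paste("decoys", p$n_decoys),
    paste("decoy_length", p$decoy_length),
    paste("mask_intervals", p$mask_intervals),
    paste("masked_positions", p$masked_positions),
    paste("excluded_families", paste(p$excluded_families, collapse = ","))
  ), side)
  invisible(path)
}

#' Build a composite reference from files
#'
#' Convenience driver: read genome, mask BED intervals, read consensus
#' decoys, drop excluded families, and write the composite FASTA the
#' aligner index is then built from.
#'
#' @param genome_fa,mask_bed,decoy_fa Input paths.
#' @param out_fa Output FASTA path.
#' @param exclude_family Families to drop from the decoy set.
#' @return The `CompositeReference`, invisibly.
#' @export
build_composite_reference <- function(genome_fa, mask_bed, decoy_fa, out_fa,
                                      exclude_family = character()) {
  genome <- read_genome_fasta(genome_fa)
  masked <- mask_intervals(genome, read_mask_bed(mask_bed))
  ref <- append_decoys(masked, read_genome_fasta(decoy_fa), exclude_family)
  write_composite(ref, out_fa)
  invisible(ref)
}

IUPAC_CODES <- Biostrings::IUPAC_CODE_MAP

#' Scan a sequence for a degenerate IUPAC motif
#'
#' Single-strand (+ strand) scan: position `p` matches when each base at
#' `p .. p+len(motif)-1` belongs to the IUPAC class of the corresponding
#' motif symbol. Used to locate the initiator (Inr) core-promoter motif
#' inside the mouse LINE-1 monomer; the default motif elsewhere in the
#' package is `"YYANWYY"`.
#'
#' @param sequence A `DNAString`/character nucleotide sequence.
#' @param motif IUPAC degenerate pattern (characters from the IUPAC code).
#' @return Sorted integer vector of 1-based match start positions.
#' @examples
#' scan_motif("GTCAGTTC", "YYANWYY")
#' @export
scan_motif <- function(sequence, motif) {
  motif <- toupper(as.character(motif))
  bad <- setdiff(strsplit(motif, "")[[1]], names(IUPAC_CODES))
  if (length(bad))
    stop("invalid IUPAC character(s) in motif: ", paste(unique(bad), collapse = ""))
  subject <- if (methods::is(sequence, "DNAString")) sequence else
    Biostrings::DNAString(toupper(as.character(sequence)))
  if (length(subject) < nchar(motif)) return(integer(0))
  m <- Biostrings::matchPattern(Biostrings::DNAString(motif), subject,
                                fixed = "subject")
  sort(BiocGenerics::start(m))
}

#' Find tandem monomer copies on a consensus
#'
#' The mouse LINE-1 5' UTR promoter is a tandem array of ~212-bp monomer
#' units. This locates non-overlapping approximate copies of a monomer on
#' a consensus by edit-distance matching (substitutions and indels),
#' tiling greedily left to right, so the promoter region can be defined
#' as the union of the reported intervals.
#'
#' @param consensus `DNAString`/character consensus sequence.
#' @param monomer Monomer sequence (length >= 50).
#' @param max_edits Maximum edit distance per copy; default
#'   `ceiling(0.1 * nchar(monomer))`.
#' @param consensus_name Contig name for the returned ranges.
#' @return A [GenomicRanges::GRanges] of monomer intervals, 5' to 3',
#'   named `monomer_1 ...`; empty when no copy is found.
#' @export
find_monomer_copies <- function(consensus, monomer,
                                max_edits = ceiling(0.1 * nchar(monomer)),
                                consensus_name = "consensus") {
  monomer <- toupper(as.character(monomer))
  stopifnot(nchar(monomer) >= 50L, max_edits >= 0L)
  subject <- if (methods::is(consensus, "DNAString")) consensus else
    Biostrings::DNAString(toupper(as.character(consensus)))
  m <- Biostrings::matchPattern(monomer, subject,
                                max.mismatch = max_edits, with.indels = TRUE)
  r <- IRanges::ranges(m)
  r <- r[order(BiocGenerics::start(r))]
  # greedy left-to-right non-overlapping tiling
  kept <- IRanges::IRanges()
  last_end <- 0L
  for (i in seq_along(r)) {
    if (BiocGenerics::start(r)[i] > last_end) {
      kept <- c(kept, r[i])
      last_end <- BiocGenerics::end(r)[i]
    }
  }
  if (length(kept) == 0L)
    return(GenomicRanges::GRanges())
  out <- GenomicRanges::GRanges(consensus_name, kept, strand = "+")
  names(out) <- paste0("monomer_", seq_along(out))
  out
}
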