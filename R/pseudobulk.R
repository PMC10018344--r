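# Pseudobulk preparation for locus-level EM quantification by an
# external tool: strip the barcode/TSO head from read 1 and shorten the
# full-length element annotation to its 5' window so only
# promoter-anchored alignments count as active expression.

#' Remove the first n bases of each read
#'
#' Drops the leading `n` bases and qualities of every read (trimmomatic
#' `HEADCROP` semantics): in 10x 5' libraries the first 46 bases of read
#' 1 are cell barcode, UMI, template-switch oligo and extra G bases, not
#' transcript. Reads of length `<= n` are dropped and counted.
#'
#' @param reads A [Biostrings::QualityScaledDNAStringSet] (or a
#'   `DNAStringSet`, in which case constant qualities are assumed absent
#'   and a plain `DNAStringSet` is returned).
#' @param n Bases to remove from the head (default 46).
#' @return The cropped read set, with attribute `n_dropped`.
#' @export
headcrop_reads <- function(reads, n = 46L) {
  stopifnot(n >= 0L)
  S4Vectors::mcols(reads) <- NULL
  keep <- Biostrings::width(reads) > n
  if (methods::is(reads, "QualityScaledDNAStringSet")) {
    seqs <- Biostrings::DNAStringSet(reads[keep])
    quals <- methods::as(Biostrings::quality(reads)[keep], "BStringSet")
    out <- Biostrings::QualityScaledDNAStringSet(
      IRanges::narrow(seqs, start = n + 1L),
      methods::as(IRanges::narrow(quals, start = n + 1L),
                  class(Biostrings::quality(reads))))
    names(out) <- names(reads)[keep]
  } else {
    out <- IRanges::narrow(reads[keep], start = n + 1L)
  }
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Headcrop a FASTQ file
#'
#' File-level wrapper around [headcrop_reads()]; gzip-tolerant in and
#' out.
#'
#' @param infile,outfile FASTQ paths.
#' @param n Bases to remove.
#' @return Invisibly, a list with `n_in`, `n_out`, `n_dropped`.
#' @export
headcrop_fastq <- function(infile, outfile, n = 46L) {
  # Biostrings warns about dropping its own fastq mcols; nothing of ours
  reads <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(infile),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  out <- headcrop_reads(reads, n)
  Biostrings::writeQualityScaledXStringSet(out, outfile,
                                           compress = grepl("\\.gz$", outfile))
  invisible(list(n_in = length(reads), n_out = length(out),
                 n_dropped = attr(out, "n_dropped")))
}

#' Shorten element annotations to their 5' window
#'
#' Replaces each locus by its 5'-most `window` bases in element
#' orientation (+ strand: `[start, start+window)`; - strand:
#' `[end-window, end)` in BED terms), so a read counts as active
#' expression only when it starts at the element promoter. Records
#' already shorter than `window` are kept full length.
#'
#' @param ann A [GenomicRanges::GRanges] of full-length element loci with
#'   strand `+` or `-` (e.g. from `rtracklayer::import(..., "BED")`).
#' @param window 5' window width in bases (default 100).
#' @return The shortened `GRanges`, strands and names preserved.
#' @export
shorten_annotation <- function(ann, window = 100L) {
  stopifnot(window >= 1L)
  ann <- methods::as(ann, "GRanges")
  if (any(GenomicRanges::strand(ann) == "*"))
    stop("shorten_annotation: record(s) without strand")
  GenomicRanges::resize(ann, width = pmin(GenomicRanges::width(ann),
                                          as.integer(window)), fix = "start")
}

#' Shorten a BED annotation file to its 5' windows
#'
#' @param infile,outfile BED paths.
#' @param window 5' window width.
#' @return `outfile`, invisibly.
#' @export
shorten_bed <- function(infile, outfile, window = 100L) {
  ann <- rtracklayer::import(infile, format = "BED")
  out <- shorten_annotation(ann, window)
  rtracklayer::export(out, outfile, format = "BED")
  invisible(outfile)
}
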