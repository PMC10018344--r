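# Alignment-record model: read cellranger-style SAM/BAM into a plain
# data.frame and interrogate CIGAR/flag/tag structure. All downstream
# filters are defined on these accessors, never on raw records.

FLAG_PAIRED <- 0x1L
FLAG_PROPER <- 0x2L
FLAG_UNMAPPED <- 0x4L
FLAG_MATE_UNMAPPED <- 0x8L
FLAG_REVERSE <- 0x10L
FLAG_FIRST <- 0x40L
FLAG_SECOND <- 0x80L
FLAG_SECONDARY <- 0x100L
FLAG_SUPPLEMENTARY <- 0x800L

flag_set <- function(flag, bit) bitwAnd(as.integer(flag), bit) != 0L

#' Construct alignment records as a data.frame
#'
#' One row per SAM record with the fields the pipeline uses: query name,
#' flag, reference contig, 1-based leftmost position, CIGAR, and the
#' NM/CB/UB tags (NA when absent). Mostly a convenience for tests and
#' simulation; [read_alignments()] produces the same layout from files.
#'
#' @param qname,flag,rname,pos,cigar Core SAM fields (`pos` 1-based).
#' @param nm Edit-distance tag value (NM), integer or NA.
#' @param cb,ub Cell / molecular barcode tags, character or NA.
#' @return A data.frame with class `l1_alignments`.
#' @export
alignment_record <- function(qname, flag, rname, pos, cigar,
                             nm = NA_integer_, cb = NA_character_,
                             ub = NA_character_) {
  df <- data.frame(qname = as.character(qname), flag = as.integer(flag),
                   rname = as.character(rname), pos = as.integer(pos),
                   cigar = as.character(cigar), nm = as.integer(nm),
                   cb = as.character(cb), ub = as.character(ub),
                   stringsAsFactors = FALSE)
  class(df) <- c("l1_alignments", "data.frame")
  df
}

#' Read alignments from SAM or BAM
#'
#' SAM input is converted to BAM on the fly with [Rsamtools::asBam()].
#' Returns the flat record table used throughout the package. Secondary
#' and supplementary alignments are retained here (flag columns expose
#' them); [pair_up()] and the filter policies exclude them.
#'
#' @param path SAM or BAM file.
#' @param contigs Optional character vector: keep only records on these
#'   reference contigs (e.g. the quantified decoys).
#' @param tags Names of the cell-barcode, molecular-barcode and
#'   edit-distance tags (change to `CR`/`UR` for uncorrected barcodes).
#' @return An `l1_alignments` data.frame (see [alignment_record()]).
#' @export
read_alignments <- function(path, contigs = NULL,
                            tags = c(cb = "CB", ub = "UB", nm = "NM")) {
  is_sam <- grepl("\\.sam$", path, ignore.case = TRUE)
  bam <- if (is_sam) {
    dest <- tempfile(fileext = "")
    Rsamtools::asBam(path, dest, overwrite = TRUE, indexDestination = FALSE)
  } else path
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar"),
    tag = unname(tags[c("nm", "cb", "ub")]))
  res <- Rsamtools::scanBam(bam, param = param)[[1]]
  df <- alignment_record(
    qname = res$qname, flag = res$flag,
    rname = as.character(res$rname), pos = res$pos, cigar = res$cigar,
    nm = res$tag[[tags[["nm"]]]] %||% rep(NA_integer_, length(res$qname)),
    cb = res$tag[[tags[["cb"]]]] %||% rep(NA_character_, length(res$qname)),
    ub = res$tag[[tags[["ub"]]]] %||% rep(NA_character_, length(res$qname)))
  if (!is.null(contigs)) df <- df[df$rname %in% contigs, , drop = FALSE]
  rownames(df) <- NULL
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Per-record CIGAR decomposition: leading/trailing clip totals (S + H),
# inserted+deleted base totals, and reference-consuming width.
cigar_table <- function(cigar) {
  ops <- GenomicAlignments::explodeCigarOps(cigar)
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)
  clip_left <- mapply(function(o, l) {
    i <- 1L; s <- 0L
    while (i <= length(o) && o[i] %in% c("S", "H")) { s <- s + l[i]; i <- i + 1L }
    s
  }, ops, lens, USE.NAMES = FALSE)
  clip_right <- mapply(function(o, l) {
    i <- length(o); s <- 0L
    while (i >= 1L && o[i] %in% c("S", "H")) { s <- s + l[i]; i <- i - 1L }
    s
  }, ops, lens, USE.NAMES = FALSE)
  indel <- mapply(function(o, l) sum(l[o %in% c("I", "D")]), ops, lens,
                  USE.NAMES = FALSE)
  data.frame(clip_left = as.integer(clip_left),
             clip_right = as.integer(clip_right),
             indel_bases = as.integer(indel),
             ref_width = GenomicAlignments::cigarWidthAlongReferenceSpace(cigar))
}

check_mapped <- function(records, op) {
  if (any(flag_set(records$flag, FLAG_UNMAPPED)) || any(records$cigar == "*"))
    stop(op, ": unmapped record(s) present")
}

#' Clip lengths at the read 5' and 3' ends
#'
#' Sums soft (S) and hard (H) clips at each alignment end, then reports
#' them in READ orientation: for a forward-strand alignment the leading
#' clip is the read-5' clip; for a reverse-strand alignment the trailing
#' clip is. In 5' chemistry the template-switch oligo and extra G bases
#' appear as a read-5' soft clip on read 1, which is why the filters
#' bound it rather than requiring zero.
#'
#' @param records An `l1_alignments` data.frame of mapped records.
#' @return data.frame with integer columns `clip5`, `clip3` (one row per
#'   record).
#' @export
clip_lengths <- function(records) {
  check_mapped(records, "clip_lengths")
  ct <- cigar_table(records$cigar)
  rev <- flag_set(records$flag, FLAG_REVERSE)
  data.frame(clip5 = ifelse(rev, ct$clip_right, ct$clip_left),
             clip3 = ifelse(rev, ct$clip_left, ct$clip_right))
}

#' Mismatch count from the NM tag
#'
#' SAM's NM tag counts mismatches plus inserted and deleted bases; the
#' filters speak only of mismatches, so indel bases are subtracted.
#' Negative results (inconsistent tags) are clamped to 0 with a warning.
#'
#' @param records An `l1_alignments` data.frame; every record must carry
#'   an NM value (a missing NM is an input error, not a filter failure).
#' @return Integer vector of mismatch counts.
#' @export
mismatch_count <- function(records) {
  if (anyNA(records$nm))
    stop("mismatch_count: NM tag missing on ", sum(is.na(records$nm)),
         " record(s)")
  mm <- records$nm - cigar_table(records$cigar)$indel_bases
  if (any(mm < 0L)) {
    warning("NM smaller than indel bases on ", sum(mm < 0L),
            " record(s); clamping mismatches to 0")
    mm[mm < 0L] <- 0L
  }
  as.integer(mm)
}

#' Reference span of mapped records
#'
#' @param records An `l1_alignments` data.frame of mapped records.
#' @return data.frame with 1-based inclusive `first` and `last` reference
#'   coordinates (last = first + reference-consuming CIGAR length - 1).
#' @export
ref_span <- function(records) {
  check_mapped(records, "ref_span")
  w <- GenomicAlignments::cigarWidthAlongReferenceSpace(records$cigar)
  data.frame(first = records$pos, last = records$pos + w - 1L)
}

#' Pair mates from a (possibly position-sorted) record stream
#'
#' Excludes secondary, supplementary and unmapped records, then joins the
#' primary first-in-pair and second-in-pair record of each query name.
#' Query names with a duplicated primary R1 or R2 are skipped and
#' counted; names with only one mapped mate become orphans.
#'
#' @param records An `l1_alignments` data.frame.
#' @return A `l1_pairs` data.frame, one row per pair, columns prefixed
#'   `r1_` / `r2_`, with a `pair_stats` attribute
#'   (`n_pairs`, `n_orphans`, `n_dup_skipped`).
#' @export
pair_up <- function(records) {
  keep <- !flag_set(records$flag, FLAG_SECONDARY) &
    !flag_set(records$flag, FLAG_SUPPLEMENTARY) &
    !flag_set(records$flag, FLAG_UNMAPPED)
  records <- records[keep, , drop = FALSE]
  is1 <- flag_set(records$flag, FLAG_FIRST)
  is2 <- flag_set(records$flag, FLAG_SECOND)
  r1 <- records[is1, , drop = FALSE]
  r2 <- records[is2, , drop = FALSE]
  dup_names <- unique(c(r1$qname[duplicated(r1$qname)],
                        r2$qname[duplicated(r2$qname)]))
  r1 <- r1[!(r1$qname %in% dup_names), , drop = FALSE]
  r2 <- r2[!(r2$qname %in% dup_names), , drop = FALSE]
  common <- intersect(r1$qname, r2$qname)
  i1 <- match(common, r1$qname)
  i2 <- match(common, r2$qname)
  cols <- c("flag", "rname", "pos", "cigar", "nm", "cb", "ub")
  out <- data.frame(qname = common, stringsAsFactors = FALSE)
  for (cl in cols) out[[paste0("r1_", cl)]] <- r1[[cl]][i1]
  for (cl in cols) out[[paste0("r2_", cl)]] <- r2[[cl]][i2]
  rownames(out) <- NULL
  class(out) <- c("l1_pairs", "data.frame")
  attr(out, "pair_stats") <- list(
    n_pairs = length(common),
    n_orphans = (nrow(r1) - length(common)) + (nrow(r2) - length(common)),
    n_dup_skipped = length(dup_names))
  out
}

# View one side of a pair table as an l1_alignments data.frame.
pair_side <- function(pairs, side = c("r1", "r2")) {
  side <- match.arg(side)
  cols <- paste0(side, "_", c("flag", "rname", "pos", "cigar", "nm", "cb", "ub"))
  df <- data.frame(qname = pairs$qname, stringsAsFactors = FALSE)
  for (cl in c("flag", "rname", "pos", "cigar", "nm", "cb", "ub"))
    df[[cl]] <- pairs[[paste0(side, "_", cl)]]
  class(df) <- c("l1_alignments", "data.frame")
  df
}
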