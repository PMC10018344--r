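# Per-cell UMI quantification: collapse passing records to distinct
# molecular barcodes per cell barcode, equalize depth across samples,
# merge samples aggr-style and profile consensus coverage.

#' Count distinct LINE-1 UMIs per cell
#'
#' Collapses policy-passing records to the number of distinct molecular
#' barcodes (UB) per cell barcode (CB): a UB seen on many passing records
#' counts once. Cells with no passing record are absent here and become
#' zero when totals are attached.
#'
#' @param evidence An `l1_alignments` data.frame of passing records (the
#'   `evidence` element of [filter_alignments()]); every record must
#'   carry CB and UB.
#' @return A `CellUmiTable` data.frame with columns `barcode` and `u_l1`.
#' @examples
#' ev <- alignment_record(c("a","b","c"), 0, "L1HS", 1, "98M",
#'                        cb = "AAAC", ub = c("u1","u1","u2"))
#' count_l1_umis(ev)
#' @export
count_l1_umis <- function(evidence) {
  if (nrow(evidence) == 0L) {
    out <- data.frame(barcode = character(0), u_l1 = integer(0))
    class(out) <- c("CellUmiTable", "data.frame")
    return(out)
  }
  if (anyNA(evidence$cb) || anyNA(evidence$ub))
    stop("count_l1_umis: record(s) without CB/UB reached counting; ",
         "the policy should have rejected them")
  key <- !duplicated(paste0(evidence$cb, "\r", evidence$ub))
  tab <- table(evidence$cb[key])
  out <- data.frame(barcode = names(tab), u_l1 = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(out$barcode), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("CellUmiTable", "data.frame")
  out
}

#' Downsample samples to even depth
#'
#' When merging runs, reads of deeper samples are subsampled so that all
#' samples sit at the depth of the shallowest one (mirroring cellranger
#' aggr). Each sample keeps a read pair independently with probability
#' `min(depths) / depth_s`; mates are kept or dropped together because
#' retention is decided per query name.
#'
#' @param record_list List of `l1_alignments` data.frames, one per sample.
#' @param depths Numeric vector of per-sample depth statistics (e.g.
#'   confidently-mapped reads per cell-called cell), same length.
#' @param seed Integer seed; the retained set is reproducible given it.
#' @return List of subsampled data.frames with a `retain_prob` attribute.
#' @export
downsample_even <- function(record_list, depths, seed = 1L) {
  stopifnot(length(record_list) == length(depths))
  if (any(depths <= 0)) stop("downsample_even: zero or negative depth")
  p <- min(depths) / depths
  out <- withr::with_seed(seed, lapply(seq_along(record_list), function(i) {
    df <- record_list[[i]]
    if (p[i] >= 1) return(df)
    qn <- unique(df$qname)
    keep <- qn[stats::rbinom(length(qn), 1L, p[i]) == 1L]
    df[df$qname %in% keep, , drop = FALSE]
  }))
  names(out) <- names(record_list)
  attr(out, "retain_prob") <- p
  out
}

#' Merge per-sample count tables aggr-style
#'
#' Rewrites barcodes as `BARCODE-i` with `i` the 1-based sample index
#' (the cellranger aggr convention) and stacks the tables.
#'
#' @param tables List of `L1CountTable`/`CellUmiTable` data.frames with a
#'   `barcode` column.
#' @param sample_ids Optional sample labels (defaults to list names or
#'   the index).
#' @return One data.frame with suffixed barcodes and a `sample` column.
#' @export
merge_samples <- function(tables, sample_ids = NULL) {
  if (is.null(sample_ids))
    sample_ids <- names(tables) %||% as.character(seq_along(tables))
  stopifnot(length(sample_ids) == length(tables), !anyDuplicated(sample_ids))
  out <- do.call(rbind, lapply(seq_along(tables), function(i) {
    df <- as.data.frame(tables[[i]])
    df$barcode <- paste0(sub("-\\d+$", "", df$barcode), "-", i)
    df$sample <- sample_ids[i]
    df
  }))
  if (anyDuplicated(out$barcode))
    stop("merge_samples: duplicate barcode after suffixing")
  rownames(out) <- NULL
  out
}

#' Per-position coverage along a consensus
#'
#' Depth profiles over the consensus, split by read role (R1/R2) and
#' strand, after dropping secondary/supplementary records and those above
#' the mismatch cutoff. Every reference-consuming position of a kept
#' record's span increments its (role, strand) array.
#'
#' @param records An `l1_alignments` data.frame on the target consensus.
#' @param consensus_length Array length.
#' @param max_mismatches Drop records with more mismatches (default 2);
#'   `Inf` keeps all.
#' @param keep_strand Optional `"+"`/`"-"` to drop the other strand
#'   (e.g. antisense removal).
#' @return A `CoverageProfile` data.frame: `pos`, `r1_plus`, `r1_minus`,
#'   `r2_plus`, `r2_minus`. Unpaired records (no R1/R2 bit) count as R1.
#' @export
coverage_profile <- function(records, consensus_length, max_mismatches = 2L,
                             keep_strand = NULL) {
  keep <- !flag_set(records$flag, FLAG_SECONDARY) &
    !flag_set(records$flag, FLAG_SUPPLEMENTARY) &
    !flag_set(records$flag, FLAG_UNMAPPED)
  records <- records[keep, , drop = FALSE]
  if (is.finite(max_mismatches) && nrow(records))
    records <- records[mismatch_count(records) <= max_mismatches, , drop = FALSE]
  if (!is.null(keep_strand) && nrow(records))
    records <- records[strand_of(records) == keep_strand, , drop = FALSE]
  role <- ifelse(flag_set(records$flag, FLAG_SECOND), "r2", "r1")
  strand <- ifelse(strand_of(records) == "+", "plus", "minus")
  out <- data.frame(pos = seq_len(consensus_length))
  sp <- if (nrow(records)) ref_span(records) else NULL
  for (ro in c("r1", "r2")) for (st in c("plus", "minus")) {
    col <- paste0(ro, "_", st)
    sel <- which(role == ro & strand == st)
    if (length(sel) == 0L) { out[[col]] <- 0L; next }
    rng <- IRanges::IRanges(sp$first[sel], pmin(sp$last[sel], consensus_length))
    cvg <- IRanges::coverage(rng, width = consensus_length)
    out[[col]] <- as.integer(cvg)
  }
  class(out) <- c("CoverageProfile", "data.frame")
  out
}

#' Attach per-cell totals to LINE-1 UMI counts
#'
#' Joins the LINE-1 counts onto the cell-called barcode universe of the
#' totals source (the filtered expression matrix): rows are emitted only
#' for cell-called barcodes, cells without LINE-1 evidence get
#' `u_l1 = 0`, and LINE-1 barcodes that were never cell-called are
#' excluded (reported in a message). Optionally drops low-depth cells.
#'
#' @param umis A `CellUmiTable` (see [count_l1_umis()]).
#' @param totals data.frame with columns `barcode` and `u_total` (see
#'   [read_totals()]).
#' @param min_total Drop cells with `u_total` below this (default 0; the
#'   published QC used 1000).
#' @return An `L1CountTable` data.frame: `barcode`, `u_l1`, `u_total`.
#' @export
attach_totals <- function(umis, totals, min_total = 0L) {
  stopifnot(all(c("barcode", "u_total") %in% names(totals)))
  if (nrow(umis) > 0L && length(intersect(umis$barcode, totals$barcode)) == 0L)
    stop("attach_totals: no barcode overlap; LINE-1 barcodes look like [",
         paste(utils::head(umis$barcode, 3), collapse = ", "),
         "] but totals barcodes look like [",
         paste(utils::head(totals$barcode, 3), collapse = ", "), "]")
  dropped <- setdiff(umis$barcode, totals$barcode)
  if (length(dropped))
    message("attach_totals: ", length(dropped),
            " LINE-1 barcode(s) not cell-called; excluded")
  out <- data.frame(barcode = totals$barcode,
                    u_l1 = umis$u_l1[match(totals$barcode, umis$barcode)],
                    u_total = totals$u_total, stringsAsFactors = FALSE)
  out$u_l1[is.na(out$u_l1)] <- 0L
  out <- out[out$u_total >= min_total, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("L1CountTable", "data.frame")
  out
}

#' Read per-cell total UMIs
#'
#' Either a cellranger-style matrix directory (`matrix.mtx`,
#' `barcodes.tsv`, `features.tsv`, gzip-tolerant) whose column sums give
#' the totals, or a two-column TSV `barcode<TAB>u_total`.
#'
#' @param path Matrix directory or TSV file.
#' @return data.frame with `barcode` and `u_total`.
#' @export
read_totals <- function(path) {
  if (dir.exists(path)) {
    pick <- function(stem) {
      for (f in file.path(path, c(stem, paste0(stem, ".gz"))))
        if (file.exists(f)) return(f)
      stop("read_totals: missing ", stem, " in ", path)
    }
    m <- Matrix::readMM(pick("matrix.mtx"))
    bc <- readLines(pick("barcodes.tsv"))
    if (ncol(m) != length(bc))
      stop("read_totals: matrix has ", ncol(m), " columns but ",
           length(bc), " barcodes")
    data.frame(barcode = bc, u_total = as.integer(Matrix::colSums(m)),
               stringsAsFactors = FALSE)
  } else {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    if (!all(c("barcode", "u_total") %in% names(df)))
      stop("read_totals: TSV needs columns 'barcode' and 'u_total'")
    df
  }
}

#' Write a cellranger-style totals matrix directory
#'
#' Emits `matrix.mtx` + `barcodes.tsv` + `features.tsv` whose column sums
#' equal the given per-cell totals (each cell's total is spread over
#' synthetic feature rows). Round-trips through [read_totals()].
#'
#' @param totals data.frame with `barcode` and `u_total`.
#' @param dir Output directory (created).
#' @param n_features Number of synthetic feature rows.
#' @param seed Seed for the multinomial allocation.
#' @return `dir`, invisibly.
#' @export
write_totals_mtx <- function(totals, dir, n_features = 50L, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- withr::with_seed(seed, vapply(totals$u_total, function(tot)
    as.numeric(stats::rmultinom(1L, tot, rep(1, n_features))),
    numeric(n_features)))
  m <- Matrix::Matrix(m, sparse = TRUE)
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(totals$barcode, file.path(dir, "barcodes.tsv"))
  writeLines(sprintf("FEAT%04d\tGene%04d\tGene Expression",
                     seq_len(n_features), seq_len(n_features)),
             file.path(dir, "features.tsv"))
  invisible(dir)
}

#' Write an L1CountTable (or CellUmiTable) as TSV
#' @param table The table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an L1CountTable TSV
#' @param path TSV written by [write_count_table()].
#' @return An `L1CountTable` data.frame.
#' @export
read_count_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  class(df) <- c("L1CountTable", "data.frame")
  df
}
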