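# Independent oracles and fixture builders, deliberately written on
# different code paths than the package implementation.

IUPAC_SET <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

# brute-force sliding-window IUPAC matcher (per-position set membership)
brute_scan <- function(seq, motif) {
  s <- strsplit(seq, "")[[1]]
  m <- strsplit(motif, "")[[1]]
  k <- length(m); n <- length(s)
  if (n < k) return(integer(0))
  hits <- integer(0)
  for (p in seq_len(n - k + 1)) {
    ok <- TRUE
    for (j in seq_len(k))
      if (!(s[p + j - 1] %in% IUPAC_SET[[m[j]]])) { ok <- FALSE; break }
    if (ok) hits <- c(hits, p)
  }
  hits
}

# regex-based overlapping IUPAC matcher (second independent route,
# fast enough for large property sweeps)
regex_scan <- function(seq, motif) {
  cls <- vapply(strsplit(motif, "")[[1]],
                function(ch) paste0("[", paste(IUPAC_SET[[ch]], collapse = ""), "]"),
                character(1))
  pat <- paste0("(?=", paste(cls, collapse = ""), ")")
  m <- gregexpr(pat, seq, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

random_seq <- function(len) paste(sample(c("A", "C", "G", "T"), len,
                                         replace = TRUE), collapse = "")

# SAM flag assembly for fixture records (vectorized)
mk_flag <- function(paired = TRUE, proper = TRUE, reverse = FALSE,
                    first = TRUE, secondary = FALSE, supplementary = FALSE,
                    unmapped = FALSE) {
  as.integer(1L * paired + 2L * proper + 4L * unmapped + 16L * reverse +
               64L * (paired & first) + 128L * (paired & !first) +
               256L * secondary + 2048L * supplementary)
}

mk_rec <- function(pos, cigar, nm = 0L, reverse = FALSE, paired = FALSE,
                   proper = FALSE, first = TRUE, rname = "L1HS",
                   qname = "q1", cb = "AAAACCCCGGGGTTTT", ub = "ACGTACGTAC",
                   secondary = FALSE) {
  alignment_record(qname,
                   mk_flag(paired, proper, reverse, first, secondary),
                   rname, pos, cigar, nm = nm, cb = cb, ub = ub)
}

# a one-row pair table from explicit r1/r2 field lists; pairs are
# proper unless a side says otherwise
mk_pair <- function(r1, r2, qname = "p1") {
  if (is.null(r1$proper)) r1$proper <- TRUE
  if (is.null(r2$proper)) r2$proper <- TRUE
  r1d <- do.call(mk_rec, c(r1, list(paired = TRUE, first = TRUE, qname = qname)))
  r2d <- do.call(mk_rec, c(r2, list(paired = TRUE, first = FALSE, qname = qname)))
  pair_up(rbind(r1d, r2d))
}

# leading/trailing clip totals parsed by regex (independent of the
# package's exploded-CIGAR walk)
regex_clips <- function(cigar) {
  lead <- 0L
  m <- regmatches(cigar, regexec("^(?:(\\d+)H)?(?:(\\d+)S)?", cigar))[[1]]
  lead <- sum(as.integer(m[-1]), na.rm = TRUE)
  m2 <- regmatches(cigar, regexec("(?:(\\d+)S)?(?:(\\d+)H)?$", cigar))[[1]]
  trail <- sum(as.integer(m2[-1]), na.rm = TRUE)
  c(lead = lead, trail = trail)
}

# reference-consuming width by summing op lengths from a regex parse
regex_ref_width <- function(cigar) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  len <- as.integer(sub("[MIDNSHP=X]$", "", ops))
  op <- sub("^\\d+", "", ops)
  sum(len[op %in% c("M", "D", "N", "=", "X")])
}

random_cigar <- function() {
  lead <- sample(0:30, 1); trail <- sample(0:30, 1)
  mid <- sample(20:120, 1)
  parts <- character(0)
  if (lead > 0) parts <- c(parts, paste0(lead, "S"))
  parts <- c(parts, paste0(mid, "M"))
  if (runif(1) < 0.3) parts <- c(parts, paste0(sample(1:5, 1), "D"),
                                 paste0(sample(5:40, 1), "M"))
  if (runif(1) < 0.3) parts <- c(parts, paste0(sample(1:5, 1), "I"),
                                 paste0(sample(5:40, 1), "M"))
  if (trail > 0) parts <- c(parts, paste0(trail, "S"))
  paste(parts, collapse = "")
}

# ---- independently written rule evaluators (the filter truth table) ----
# Straight boolean transcriptions of the published rule lists; no shared
# code with the package's ordered-reason machinery.

truth_human5 <- function(pos1, clip5_1, clip3_1, mm1, rev1, proper,
                         clip5_2, clip3_2, mm2, rev2, has_cb, has_ub,
                         tss_win = 20, max_clip5 = 19, max_mm = 2) {
  proper &&
    pos1 >= 1 && pos1 <= tss_win &&
    clip5_1 <= max_clip5 && clip3_1 == 0 && mm1 <= max_mm && !rev1 &&
    clip5_2 == 0 && clip3_2 == 0 && mm2 <= max_mm && rev2 &&
    has_cb && has_ub
}

truth_mouse5 <- function(pos1, in_monomer, clip5_1, clip3_1, mm1, rev1,
                         proper, clip5_2, clip3_2, mm2, rev2, has_cb,
                         has_ub, max_clip5 = 20, max_mm = 2) {
  proper && in_monomer &&
    clip5_1 <= max_clip5 && clip3_1 == 0 && mm1 <= max_mm && !rev1 &&
    clip5_2 == 0 && clip3_2 == 0 && mm2 <= max_mm && rev2 &&
    has_cb && has_ub
}

truth_window <- function(pos, clip_l, clip_r, mm, strand, has_cb, has_ub,
                         win, sense = "-", max_mm = 2) {
  clip_l == 0 && clip_r == 0 && mm <= max_mm &&
    pos >= 1 && pos <= win && strand == sense && has_cb && has_ub
}

truth_human3 <- function(first, last, clip_l, clip_r, mm, has_cb, has_ub,
                         L, polya, win = 1000, max_mm = 2) {
  clip_l == 0 && clip_r == 0 && mm <= max_mm &&
    first >= L - win + 1 && last <= L - polya && has_cb && has_ub
}
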