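test_that("UMI counting is distinct-UB-per-CB set cardinality", {
  ev <- alignment_record(c("a", "b", "c"), 0L, "L1HS", 1L, "98M",
                         cb = "CELL1", ub = c("u1", "u1", "u2"))
  got <- count_l1_umis(ev)
  expect_equal(got$u_l1, 2L)

  expect_equal(nrow(count_l1_umis(ev[0, ])), 0L)
  expect_error(count_l1_umis(alignment_record("q", 0L, "L1HS", 1, "98M")),
               "CB/UB")

  # 10,000 random (CB,UB) records vs an independent group-by-distinct oracle
  set.seed(401)
  n <- 10000
  df <- alignment_record(sprintf("r%05d", 1:n), 0L, "L1HS", 1L, "98M",
                         cb = sample(sprintf("CELL%02d", 1:40), n, TRUE),
                         ub = sample(sprintf("u%03d", 1:300), n, TRUE))
  got <- count_l1_umis(df)
  oracle <- tapply(df$ub, df$cb, function(u) length(unique(u)))
  expect_equal(got$u_l1, as.integer(oracle[got$barcode]),
               ignore_attr = TRUE)

  # order-invariance and idempotence under record duplication
  shuf <- df[sample(n), ]
  expect_equal(count_l1_umis(shuf), got)
  expect_equal(count_l1_umis(rbind(df, df)), got)
})

test_that("downsampling equalizes depth, keeps mates together, reproduces", {
  mk_sample <- function(n, prefix) {
    qn <- rep(sprintf("%s%04d", prefix, 1:n), each = 2)
    alignment_record(qn, rep(c(99L, 147L), n), "L1HS", 1L, "50M",
                     cb = "C", ub = "u")
  }
  s1 <- mk_sample(500, "a"); s2 <- mk_sample(500, "b")

  # equal depths: identity
  same <- downsample_even(list(s1, s2), c(100, 100), seed = 9)
  expect_identical(same[[1]], s1)
  expect_equal(attr(same, "retain_prob"), c(1, 1))

  # depths (100, 200): sample 2 retains ~50% of pairs, binomial +/- 3 sigma
  ds <- downsample_even(list(s1, s2), c(100, 200), seed = 9)
  kept_pairs <- length(unique(ds[[2]]$qname))
  sigma <- sqrt(500 * 0.5 * 0.5)
  expect_true(abs(kept_pairs - 250) <= 3 * sigma)
  # mates kept or dropped together
  expect_true(all(table(ds[[2]]$qname) == 2L))
  # bit-identical rerun under the same seed
  ds2 <- downsample_even(list(s1, s2), c(100, 200), seed = 9)
  expect_identical(ds[[2]]$qname, ds2[[2]]$qname)

  expect_equal(attr(downsample_even(list(s1, s1, s1), c(50, 100, 150), 1),
                    "retain_prob"), c(1, 0.5, 1/3))
  expect_error(downsample_even(list(s1), 0, 1), "depth")

  # retained fraction within 3 binomial sigma across 100 seeds
  fr <- vapply(1:100, function(sd)
    length(unique(downsample_even(list(s1, s2), c(100, 200), sd)[[2]]$qname)),
    numeric(1))
  expect_true(all(abs(fr - 250) <= 3 * sigma))
})

test_that("aggr-style merging suffixes barcodes and conserves counts", {
  t1 <- data.frame(barcode = c("ACGT", "TTTT"), u_l1 = c(3L, 1L))
  t2 <- data.frame(barcode = c("ACGT", "GGGG"), u_l1 = c(2L, 5L))
  m <- merge_samples(list(s1 = t1, s2 = t2))
  expect_equal(m$barcode, c("ACGT-1", "TTTT-1", "ACGT-2", "GGGG-2"))
  expect_equal(sum(m$u_l1), sum(t1$u_l1) + sum(t2$u_l1))
  expect_equal(m$sample, c("s1", "s1", "s2", "s2"))
  expect_error(merge_samples(list(data.frame(barcode = c("A", "A"),
                                             u_l1 = 1:2))), "duplicate")
})

test_that("coverage profiles equal a brute-force per-base tally", {
  one <- mk_rec(1, "100M")
  cp <- coverage_profile(one, 200)
  expect_equal(cp$r1_plus, c(rep(1L, 100), rep(0L, 100)))
  expect_true(all(cp$r2_plus == 0))

  set.seed(402)
  n <- 200; L <- 500
  recs <- alignment_record(
    sprintf("r%03d", 1:n),
    sample(c(99L, 147L, 83L, 163L), n, TRUE),
    "L1HS", sample(1:(L - 100), n, TRUE),
    sprintf("%dM", sample(50:100, n, TRUE)),
    nm = sample(0:3, n, TRUE), cb = "C", ub = "u")
  cp <- coverage_profile(recs, L, max_mismatches = 2)
  # naive O(N*L) oracle
  tally <- matrix(0L, L, 4, dimnames = list(NULL, c("r1_plus", "r1_minus",
                                                    "r2_plus", "r2_minus")))
  for (i in seq_len(n)) {
    if (recs$nm[i] > 2) next
    w <- as.integer(sub("M", "", recs$cigar[i]))
    role <- if (bitwAnd(recs$flag[i], 0x80L) != 0L) "r2" else "r1"
    st <- if (bitwAnd(recs$flag[i], 0x10L) != 0L) "minus" else "plus"
    col <- paste0(role, "_", st)
    span <- recs$pos[i]:(recs$pos[i] + w - 1L)
    tally[span, col] <- tally[span, col] + 1L
  }
  for (col in colnames(tally)) expect_equal(cp[[col]], unname(tally[, col]))

  # conservation: column sums equal total kept reference-consuming length
  kept <- recs$nm <= 2
  expect_equal(sum(cp$r1_plus) + sum(cp$r1_minus) + sum(cp$r2_plus) +
                 sum(cp$r2_minus),
               sum(as.integer(sub("M", "", recs$cigar[kept]))))
  # an NM=3 read contributes nothing anywhere
  just3 <- recs[recs$nm == 3, ][1, ]
  expect_true(all(coverage_profile(just3, L, max_mismatches = 2)[, -1] == 0))
})

test_that("totals attachment fills zeros, drops QC failures, flags mismatches", {
  umis <- structure(data.frame(barcode = "B1", u_l1 = 4L),
                    class = c("CellUmiTable", "data.frame"))
  totals <- data.frame(barcode = c("B1", "B2", "B3"),
                       u_total = c(2000L, 900L, 1500L))
  tab <- attach_totals(umis, totals)
  expect_equal(tab$u_l1, c(4L, 0L, 0L))
  # published QC: cells under 1000 molecules removed
  qc <- attach_totals(umis, totals, min_total = 1000)
  expect_equal(qc$barcode, c("B1", "B3"))
  # L1 barcode that was never cell-called is excluded with a message
  umis2 <- structure(data.frame(barcode = c("B1", "BX"), u_l1 = c(4L, 7L)),
                     class = c("CellUmiTable", "data.frame"))
  expect_message(tab2 <- attach_totals(umis2, totals), "not cell-called")
  expect_false("BX" %in% tab2$barcode)
  expect_equal(sum(tab2$u_l1), 4L)
  # empty intersection is a hard error with diagnostic keys
  expect_error(attach_totals(
    structure(data.frame(barcode = "ZZZ", u_l1 = 1L),
              class = c("CellUmiTable", "data.frame")), totals),
    "no barcode overlap")
})

test_that("matrix-directory totals round-trip through MTX", {
  totals <- data.frame(barcode = sprintf("BC%02d-1", 1:8),
                       u_total = c(1200L, 800L, 1500L, 1L, 999L, 4000L,
                                   2500L, 10L))
  dir <- tempfile()
  write_totals_mtx(totals, dir, n_features = 20, seed = 3)
  back <- read_totals(dir)
  expect_equal(back, totals)
  # TSV route
  tsv <- tempfile(fileext = ".tsv")
  utils::write.table(totals, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_totals(tsv), totals)
})
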