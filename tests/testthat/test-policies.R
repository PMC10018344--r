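pol_h5 <- chemistry_policy("human_5p_paired", "L1HS")

test_that("terminal poly-A runs are detected with one tolerated non-A", {
  expect_equal(detect_polya_run("ACGTACGT"), 0L)
  expect_equal(detect_polya_run(paste0(random_seq(50), strrep("A", 30))), 30L)
  # one interior non-A is absorbed into the run
  expect_equal(detect_polya_run(paste0("CCCC", strrep("A", 10), "G",
                                       strrep("A", 8))), 19L)
  # fewer than 5 A's is no run; a trailing non-A is never part of the run
  expect_equal(detect_polya_run("CCCCAAAA"), 0L)
  expect_equal(detect_polya_run(paste0("CC", strrep("A", 10), "G")), 10L)
})

test_that("human 5' paired rules pass and fail on the documented bounds", {
  ok <- mk_pair(list(pos = 3, cigar = "18S80M", nm = 1),
                list(pos = 150, cigar = "100M", nm = 0, reverse = TRUE,
                     proper = TRUE))
  d <- evaluate_human5_pair(ok, pol_h5)
  expect_true(d$pass)
  expect_equal(d$reason, "ok")

  # start just outside the 20-base TSS window
  far <- mk_pair(list(pos = 25, cigar = "18S80M", nm = 1),
                 list(pos = 150, cigar = "100M", reverse = TRUE, proper = TRUE))
  expect_equal(evaluate_human5_pair(far, pol_h5)$reason,
               "r1_start_outside_window")
  expect_true(evaluate_human5_pair(
    mk_pair(list(pos = 20, cigar = "18S80M"),
            list(pos = 150, cigar = "100M", reverse = TRUE, proper = TRUE)),
    pol_h5)$pass)

  # any clipping on read 2 rejects
  clip2 <- mk_pair(list(pos = 3, cigar = "18S80M"),
                   list(pos = 150, cigar = "95M5S", reverse = TRUE,
                        proper = TRUE))
  expect_equal(evaluate_human5_pair(clip2, pol_h5)$reason, "r2_clipped")

  # human bound: 19 clipped bases pass, 20 fail ("fewer than 20")
  c19 <- mk_pair(list(pos = 3, cigar = "19S80M"),
                 list(pos = 150, cigar = "100M", reverse = TRUE, proper = TRUE))
  c20 <- mk_pair(list(pos = 3, cigar = "20S80M"),
                 list(pos = 150, cigar = "100M", reverse = TRUE, proper = TRUE))
  expect_true(evaluate_human5_pair(c19, pol_h5)$pass)
  expect_equal(evaluate_human5_pair(c20, pol_h5)$reason, "r1_5clip_exceeded")

  # strand rule: R1 must be forward, R2 reverse
  ss <- mk_pair(list(pos = 3, cigar = "18S80M"),
                list(pos = 150, cigar = "100M", proper = TRUE))
  expect_equal(evaluate_human5_pair(ss, pol_h5)$reason, "wrong_strand")

  # proper-pair bit and barcodes
  np <- mk_pair(list(pos = 3, cigar = "18S80M", proper = FALSE),
                list(pos = 150, cigar = "100M", reverse = TRUE, proper = FALSE))
  expect_equal(evaluate_human5_pair(np, pol_h5)$reason, "not_proper_pair")
  nb <- mk_pair(list(pos = 3, cigar = "18S80M", ub = NA),
                list(pos = 150, cigar = "100M", reverse = TRUE, proper = TRUE))
  expect_equal(evaluate_human5_pair(nb, pol_h5)$reason, "missing_barcode")
})

test_that("window mode start rule flips exactly between the 150 and 500 cutoffs", {
  p150 <- chemistry_policy("fiveprime_window", "L1HS", window_len = 150)
  p500 <- chemistry_policy("fiveprime_window", "L1HS", window_len = 500)
  near <- mk_rec(40, "90M", reverse = TRUE)
  mid <- mk_rec(200, "90M", reverse = TRUE)
  expect_true(evaluate_window_read(near, p150)$pass)
  expect_true(evaluate_window_read(near, p500)$pass)
  expect_equal(evaluate_window_read(mid, p150)$reason,
               "r1_start_outside_window")
  expect_true(evaluate_window_read(mid, p500)$pass)
  # antisense reads are filtered out
  anti <- mk_rec(40, "90M")
  expect_equal(evaluate_window_read(anti, p150)$reason, "wrong_strand")
})

test_that("3'-mode keeps the final kilobase but not the poly-A stretch", {
  set.seed(301)
  cons <- paste0(random_seq(1970), strrep("A", 30))  # L = 2000, polyA = 30
  p3 <- chemistry_policy("human_3p", "L1HS", consensus = cons)
  expect_equal(p3$polyA_exclusion_len, 30L)
  inside <- mk_rec(1200, "90M", nm = 1)
  expect_true(evaluate_human3_read(inside, p3)$pass)
  # overlapping the terminal poly-A run
  tail <- mk_rec(1950, "50M")
  expect_equal(evaluate_human3_read(tail, p3)$reason, "in_polyA")
  # consensus midpoint is before the final kilobase
  mid <- mk_rec(900, "90M")
  expect_equal(evaluate_human3_read(mid, p3)$reason, "outside_3p_window")
  clip <- mk_rec(1200, "85M5S")
  expect_equal(evaluate_human3_read(clip, p3)$reason, "r2_clipped")
})

test_that("mouse mode requires read-1 starts inside a monomer, clip bound inclusive", {
  mono <- GenomicRanges::GRanges("L1MdTf_I", IRanges::IRanges(
    start = c(1, 213, 425), width = 212), strand = "+")
  pm <- chemistry_policy("mouse_5p_paired", "L1MdTf_I",
                         monomer_intervals = mono)
  in2 <- mk_pair(list(pos = 250, cigar = "15S135M", rname = "L1MdTf_I"),
                 list(pos = 500, cigar = "90M", reverse = TRUE, proper = TRUE,
                      rname = "L1MdTf_I"))
  expect_true(evaluate_mouse5_pair(in2, pm)$pass)
  body <- mk_pair(list(pos = 700, cigar = "15S135M", rname = "L1MdTf_I"),
                  list(pos = 900, cigar = "90M", reverse = TRUE, proper = TRUE,
                       rname = "L1MdTf_I"))
  expect_equal(evaluate_mouse5_pair(body, pm)$reason, "outside_monomer")

  # mouse clip bound is inclusive at 20 where the human bound is not
  c20 <- function(pol_rname) mk_pair(
    list(pos = 10, cigar = "20S130M", rname = pol_rname),
    list(pos = 300, cigar = "90M", reverse = TRUE, proper = TRUE,
         rname = pol_rname))
  expect_true(evaluate_mouse5_pair(c20("L1MdTf_I"), pm)$pass)
  expect_false(evaluate_human5_pair(c20("L1HS"), pol_h5)$pass)
  c21 <- mk_pair(list(pos = 10, cigar = "21S129M", rname = "L1MdTf_I"),
                 list(pos = 300, cigar = "90M", reverse = TRUE, proper = TRUE,
                      rname = "L1MdTf_I"))
  expect_equal(evaluate_mouse5_pair(c21, pm)$reason, "r1_5clip_exceeded")
  expect_error(chemistry_policy("mouse_5p_paired", "L1MdTf_I"),
               "monomer_intervals")
})

test_that("relaxing mismatch or window bounds never turns a pass into a fail", {
  set.seed(302)
  for (i in 1:40) {
    pr <- mk_pair(list(pos = sample(1:40, 1),
                       cigar = sprintf("%dS%dM", sample(0:25, 1), 100),
                       nm = sample(0:4, 1),
                       reverse = runif(1) < 0.2),
                  list(pos = sample(100:300, 1), cigar = "90M",
                       nm = sample(0:4, 1),
                       reverse = runif(1) < 0.8, proper = TRUE))
    strict <- chemistry_policy("human_5p_paired", "L1HS",
                               tss_window_len = 20, max_mismatches = 2)
    loose <- chemistry_policy("human_5p_paired", "L1HS",
                              tss_window_len = 40, max_mismatches = 5)
    if (evaluate_human5_pair(pr, strict)$pass)
      expect_true(evaluate_human5_pair(pr, loose)$pass)
  }
})

test_that("off-target records are rejected before any other rule", {
  off <- mk_pair(list(pos = 3, cigar = "18S80M", rname = "chrA"),
                 list(pos = 150, cigar = "100M", reverse = TRUE, proper = TRUE,
                      rname = "chrA"))
  expect_equal(evaluate_human5_pair(off, pol_h5)$reason, "off_target_contig")
  offw <- mk_rec(40, "90M", reverse = TRUE, rname = "chrB")
  expect_equal(evaluate_window_read(
    offw, chemistry_policy("fiveprime_window", "L1HS"))$reason,
    "off_target_contig")
})
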