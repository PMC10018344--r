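test_that("masking replaces exactly the interval union and nothing else", {
  set.seed(101)
  asm <- Biostrings::DNAStringSet(c(chrT = random_seq(100), chrU = random_seq(80)))
  # identity on empty interval set
  same <- mask_intervals(asm, GenomicRanges::GRanges())
  expect_identical(as.character(same), as.character(asm))

  gr <- GenomicRanges::GRanges(c("chrT", "chrT"),
                               IRanges::IRanges(c(11, 16), c(20, 30)))
  masked <- mask_intervals(asm, gr)
  s <- strsplit(as.character(masked[["chrT"]]), "")[[1]]
  # brute-force per-position union oracle
  covered <- sort(unique(c(11:20, 16:30)))
  expect_equal(which(s == "N"), covered)
  expect_length(covered, 20)
  expect_identical(paste(s[-covered], collapse = ""),
                   paste(strsplit(as.character(asm[["chrT"]]), "")[[1]][-covered],
                         collapse = ""))
  expect_identical(as.character(masked[["chrU"]]), as.character(asm[["chrU"]]))
  # lengths and order preserved
  expect_identical(lengths(masked), lengths(asm))
  expect_identical(names(masked), names(asm))
  # idempotence
  expect_identical(as.character(mask_intervals(masked, gr)),
                   as.character(masked))
})

test_that("masking rejects malformed intervals", {
  asm <- Biostrings::DNAStringSet(c(chrT = strrep("ACGT", 25)))
  expect_error(mask_intervals(asm, GenomicRanges::GRanges(
    "chrX", IRanges::IRanges(1, 5))), "unknown contig")
  expect_error(mask_intervals(asm, GenomicRanges::GRanges(
    "chrT", IRanges::IRanges(50, 200))), "outside")
})

test_that("appending decoys conserves lengths, order and content", {
  set.seed(102)
  genome <- Biostrings::DNAStringSet(c(chr1 = random_seq(300)))
  decoys <- Biostrings::DNAStringSet(c("L1HS#LINE/L1" = random_seq(150),
                                       "L1PA2#LINE/L1" = random_seq(140)))
  ref <- append_decoys(genome, decoys)
  all_seq <- composite_sequences(ref)
  expect_identical(names(all_seq), c("chr1", "L1HS#LINE/L1", "L1PA2#LINE/L1"))
  expect_equal(sum(lengths(all_seq)), 300 + 150 + 140)

  # FASTA round trip preserves sequence exactly
  fa <- tempfile(fileext = ".fa")
  write_composite(ref, fa)
  back <- read_genome_fasta(fa)
  expect_identical(as.character(back), as.character(all_seq))
  expect_true(file.exists(paste0(fa, ".provenance.txt")))

  # name collision is fatal; empty decoy list is a valid degenerate case
  expect_error(append_decoys(genome, Biostrings::DNAStringSet(c(chr1 = "ACGT"))),
               "collides")
  empty <- append_decoys(genome, Biostrings::DNAStringSet())
  expect_equal(length(composite_sequences(empty)), 1L)

  # family-based exclusion
  mouse <- Biostrings::DNAStringSet(c(L1MdTf_I = random_seq(100),
                                      L1MdTf_II = random_seq(100),
                                      L1MdGf_II = random_seq(100)))
  kept <- append_decoys(genome, mouse,
                        exclude_family = c("L1MdTf_II", "L1MdGf_II"))
  expect_identical(names(kept$decoys), "L1MdTf_I")
})

test_that("motif scanning matches per-position IUPAC membership", {
  expect_identical(scan_motif("AAAA", "C"), integer(0))
  expect_identical(scan_motif("TCAGTT", "YYANWYY"), integer(0))
  expect_identical(scan_motif("GTCAGTTC", "YYANWYY"),
                   brute_scan("GTCAGTTC", "YYANWYY"))
  expect_error(scan_motif("ACGT", "QQ"), "IUPAC")

  set.seed(103)
  for (i in 1:60) {
    s <- random_seq(500)
    motif <- paste(sample(names(IUPAC_SET), sample(4:8, 1), replace = TRUE),
                   collapse = "")
    expect_identical(scan_motif(s, motif), regex_scan(s, motif))
  }
  # regex oracle itself agrees with the explicit loop on a spot check
  s <- random_seq(200)
  expect_identical(regex_scan(s, "YYANWYY"), brute_scan(s, "YYANWYY"))
})

test_that("monomer copies are recovered by greedy edit-distance tiling", {
  set.seed(104)
  monomer <- random_seq(212)
  body <- random_seq(1000)
  exact <- paste0(strrep(monomer, 3), body)
  hits <- find_monomer_copies(exact, monomer, max_edits = 0)
  expect_equal(BiocGenerics::start(hits), c(1, 213, 425))
  expect_equal(BiocGenerics::width(hits), rep(212, 3))

  # copies carrying 2 substitutions each are found at max_edits = 3,
  # and each reported interval is within edit distance 3 of the monomer
  mutate2 <- function(x) {
    s <- strsplit(x, "")[[1]]
    at <- sample(length(s), 2)
    s[at] <- vapply(s[at], function(b) sample(setdiff(c("A","C","G","T"), b), 1), "")
    paste(s, collapse = "")
  }
  cons <- paste0(mutate2(monomer), mutate2(monomer), mutate2(monomer), body)
  hits2 <- find_monomer_copies(cons, monomer, max_edits = 3)
  expect_equal(BiocGenerics::start(hits2), c(1, 213, 425))
  for (i in seq_along(hits2)) {
    sub <- substr(cons, BiocGenerics::start(hits2)[i], BiocGenerics::end(hits2)[i])
    expect_lte(drop(utils::adist(sub, monomer)), 3)  # DP edit-distance oracle
  }

  # absent monomer yields an empty result
  expect_length(find_monomer_copies(random_seq(800), monomer, max_edits = 0), 0)

  # max_edits = 0 agrees with exact substring search on random plants
  for (i in 1:10) {
    mono <- random_seq(60)
    n_cop <- sample(1:4, 1)
    cons2 <- paste0(paste(rep(mono, n_cop), collapse = ""), random_seq(300))
    got <- find_monomer_copies(cons2, mono, max_edits = 0)
    exp_starts <- (seq_len(n_cop) - 1) * 60 + 1
    expect_equal(BiocGenerics::start(got)[seq_len(n_cop)], exp_starts)
  }
})
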