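guide <- guide_spec("ATGGGTGTTCTTCTGGCTGT")

test_that("guide specification validates its inputs", {
  expect_error(guide_spec("ATG"), "20 nt")
  expect_error(guide_spec("ATGGGTGTTCTTCTGGCTGN"), "A/C/G/T")
  expect_error(guide_spec("ATGGGTGTTCTTCTGGCTGT", pam = "XGG"), "IUPAC")
  g <- guide_spec("atgggtgttcttctggctgt", max_mismatches = 3)
  expect_equal(g$protospacer, "ATGGGTGTTCTTCTGGCTGT")
})

test_that("planted exact protospacer+PAM is found once on the + strand", {
  set.seed(91)
  left <- paste(sample(c("A", "C"), 500, replace = TRUE), collapse = "")
  right <- paste(sample(c("A", "C"), 477, replace = TRUE), collapse = "")
  genome <- Biostrings::DNAStringSet(c(
    chr1 = paste0(left, "ATGGGTGTTCTTCTGGCTGT", "AGG", right)))
  hits <- scan_genome(genome, guide)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 501L)
  expect_equal(hits$end, 520L)
  expect_equal(hits$strand, "+")
  expect_equal(hits$mismatches, 0L)
  expect_equal(hits$matched_seq, "ATGGGTGTTCTTCTGGCTGT")
})

test_that("reverse-complement planting is reported on the - strand in guide orientation", {
  set.seed(92)
  bg <- paste(sample(c("A", "C"), 300, replace = TRUE), collapse = "")
  insert <- clonemut:::revcomp_chr("ATGGGTGTTCTTCTGGCTGTAGG")
  genome <- Biostrings::DNAStringSet(c(chr1 = paste0(bg, insert, bg)))
  hits <- scan_genome(genome, guide)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$strand, "-")
  expect_equal(hits$matched_seq, "ATGGGTGTTCTTCTGGCTGT")
  expect_equal(hits$mismatches, 0L)
  # protospacer span: PAM occupies the first 3 inserted bases on +
  expect_equal(hits$start, 304L)
  expect_equal(hits$end, 323L)
})

test_that("scanner equals the naive oracle on random genomes", {
  for (seed in 1:6) {
    genome <- random_genome(c(4000, 2500), seed = seed)
    g <- guide_spec("ATGGGTGTTCTTCTGGCTGT", max_mismatches = 8)
    mine <- scan_genome(genome, g)
    oracle <- oracle_scan_genome(genome, g)
    if (is.null(oracle)) {
      expect_equal(nrow(mine), 0L)
    } else {
      expect_equal(mine[c("chrom", "start", "end", "strand", "matched_seq",
                          "mismatches")], oracle)
    }
  }
})

test_that("scanner recovers simulator-planted degenerate sites exactly", {
  p <- simulator_params(genome_size = 3e4, n_contigs = 3,
                        planted_offtarget_count = 10,
                        offtarget_mismatches = c(1, 2, 3, 4, 5))
  ref <- simulate_reference(p, seed = 17)
  hits <- scan_genome(ref$genome, ref$guide)
  for (i in seq_len(nrow(ref$sites))) {
    hit <- hits[hits$chrom == ref$sites$chrom[i] &
                  hits$start == ref$sites$start[i] &
                  hits$strand == ref$sites$strand[i], ]
    expect_equal(nrow(hit), 1L)
    expect_equal(hit$mismatches, ref$sites$mismatches[i])
  }
})

test_that("strand involution: reverse-complementing the genome mirrors hits", {
  genome <- random_genome(1500, seed = 55)
  g <- guide_spec("ATGGGTGTTCTTCTGGCTGT", max_mismatches = 9)
  fwd <- scan_genome(genome, g)
  rc <- Biostrings::DNAStringSet(stats::setNames(
    as.character(Biostrings::reverseComplement(genome[[1]])), "ctg1"))
  bwd <- scan_genome(rc, g)
  expect_equal(nrow(fwd), nrow(bwd))
  expect_equal(sort(paste(fwd$mismatches, fwd$matched_seq)),
               sort(paste(bwd$mismatches, bwd$matched_seq)))
  L <- Biostrings::width(genome[1])
  expect_setequal(bwd$start, L - fwd$end + 1L)
  expect_setequal(chartr("+-", "-+", bwd$strand), fwd$strand)
})

test_that("site count is non-decreasing in the mismatch budget", {
  genome <- random_genome(20000, seed = 77)
  counts <- vapply(5:9, function(mm)
    nrow(scan_genome(genome, guide_spec("ATGGGTGTTCTTCTGGCTGT",
                                        max_mismatches = mm))), integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("candidate-site matching honours the +/- 50 bp boundary", {
  sites <- data.frame(chrom = "chr1", start = 1000L, end = 1019L,
                      strand = "+", matched_seq = "x", mismatches = 0L,
                      stringsAsFactors = FALSE)
  # PAM span runs to 1022; candidates at the edge, past it, and inside
  cands <- data.frame(chrom = "chr1", pos = c(1072L, 1073L, 1010L, 950L, 949L))
  m <- match_candidates(cands, sites, window = 50)
  expect_setequal(m$candidate, c(1L, 3L, 4L))
  expect_equal(m$distance[m$candidate == 1L], 50L)
  expect_equal(m$distance[m$candidate == 3L], 0L)
  expect_equal(m$distance[m$candidate == 4L], 50L)
  # different contig never matches
  m2 <- match_candidates(data.frame(chrom = "chr2", pos = 1010L), sites)
  expect_equal(nrow(m2), 0L)
})

test_that("flank homology finds a planted adjacent protospacer and matches brute force", {
  set.seed(13)
  bg <- paste(sample(c("A", "C"), 400, replace = TRUE), collapse = "")
  genome <- Biostrings::DNAStringSet(c(
    chr1 = paste0(substr(bg, 1, 200), "ATGGGTGTTCTTCTGGCTGTTGG",
                  substr(bg, 201, 400))))
  # candidate 10 bp downstream of the planted site
  fh <- flank_homology("chr1", 233, genome, guide)
  expect_equal(fh$best_pam$mismatches, 0L)
  expect_equal(fh$best_pam$start, 201L)
  expect_equal(fh$best_pam$strand, "+")
  expect_false(fh$truncated)

  # random-window case: compare the best PAM-adjacent hit to brute force
  genome2 <- random_genome(2000, seed = 99)
  fh2 <- flank_homology("ctg1", 800, genome2, guide, flank = 75)
  chars <- strsplit(as.character(genome2[[1]]), "")[[1]]
  win <- chars[725:875]
  proto <- strsplit(guide$protospacer, "")[[1]]
  best <- Inf
  for (strand in c("+", "-")) {
    sc <- if (strand == "+") win else oracle_revcomp(win)
    for (off in 1:(length(sc) - 22)) {
      if (!(sc[off + 21] == "G" && sc[off + 22] == "G")) next
      best <- min(best, sum(sc[off:(off + 19)] != proto))
    }
  }
  expect_equal(fh2$best_pam$mismatches, best)
  expect_lte(fh2$best_any$mismatches, best)
  # truncation at the contig edge is flagged
  fh3 <- flank_homology("ctg1", 10, genome2, guide)
  expect_true(fh3$truncated)
})

test_that("interval arithmetic is 1-based inclusive", {
  expect_equal(interval_length(57340856, 57349715), 8860)
  expect_equal(interval_length(5, 5), 1)
  expect_equal(interval_length(1, 10), 10)
  expect_error(interval_length(10, 9), "end must be")
})
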