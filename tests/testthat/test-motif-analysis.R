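test_that("scan_kmer finds forward and reverse-strand cores", {
  hits <- scan_kmer("GGCACTTGG", "CACTT")
  expect_equal(nrow(hits), 1)
  expect_equal(hits$offset, 3)  # 1-based offset
  expect_equal(hits$strand, "+")
  rc <- scan_kmer("AAGTG", "CACTT")
  expect_equal(nrow(rc), 1)
  expect_equal(rc$strand, "-")
  expect_equal(nrow(scan_kmer("NNNNNNNN", "CACTT")), 0)
})

test_that("scan_kmer equals the naive oracle and is strand-symmetric", {
  set.seed(5)
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE),
               collapse = "")
    for (k in c("CACTT", "TAAT", "CCGG")) {
      expect_equal(nrow(scan_kmer(s, k)), oracle_scan_count(s, k))
      # scanning the reverse complement preserves the total count
      src <- chartr("ACGT", "TGCA",
                    paste(rev(strsplit(s, "")[[1]]), collapse = ""))
      expect_equal(nrow(scan_kmer(src, k)), nrow(scan_kmer(s, k)))
    }
  }
})

test_that("flank_preference reads flanks on the matched strand", {
  ft <- flank_preference("ACCACTTAG", core = "CACTT")
  expect_equal(ft["C", "five_prime"], 1)
  expect_equal(ft["A", "three_prime"], 1)
  expect_equal(sum(ft[, "five_prime"]), 1)
  # reverse-strand occurrence: revcomp(ACCACTTAG) = CTAAGTGGT contains the
  # core on the minus strand with the same flanks after complementing
  ftr <- flank_preference("CTAAGTGGT", core = "CACTT")
  expect_equal(ftr["C", "five_prime"], 1)
  expect_equal(ftr["A", "three_prime"], 1)
  # edge occurrence contributes only the flank it has
  fte <- flank_preference("CACTTG", core = "CACTT")
  expect_equal(sum(fte[, "five_prime"]), 0)
  expect_equal(sum(fte[, "three_prime"]), 1)
  expect_error(flank_preference("GGGG", core = "CACTT"), "no occurrence")
})

test_that("planted 5'-C flanks dominate the flank table", {
  set.seed(31)
  u <- simulate_peak_universe(n_shared = 60, n_lost = 0, n_gained = 0,
                              peak_width = 200, seed = 31,
                              planted_motifs = list(
                                list(kmer = "CCACTTA", fraction = 0.9,
                                     copies = 1)))
  seqs <- u$sequences[u$truth$label == "shared"]
  ft <- flank_preference(seqs, core = "CACTT")
  expect_equal(rownames(ft)[which.max(ft[, "five_prime"])], "C")
  # conservation: column sums equal flanked-hit counts
  expect_true(all(colSums(ft) <= sum(count_kmer(seqs, "CACTT"))))
})

test_that("motif classes follow the documented precedence and strand invariance", {
  expect_equal(assign_motif_class("CCACTTAA"), "high_NKE")
  expect_equal(assign_motif_class("ACACTTTG"), "low_NKE")
  expect_equal(assign_motif_class("GCTAATTA"), "HOX_like")
  expect_equal(assign_motif_class("GGGGGGGG"), "other")
  # reverse complement gets the same class
  set.seed(8)
  kmers <- replicate(50, paste(sample(c("A", "C", "G", "T"), 8,
                                      replace = TRUE), collapse = ""))
  rcs <- vapply(kmers, function(k) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(k, "")[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
  expect_equal(assign_motif_class(kmers), assign_motif_class(rcs))
  # totality: every 8-mer gets exactly one of the four labels
  expect_true(all(assign_motif_class(kmers) %in%
                    c("high_NKE", "low_NKE", "HOX_like", "other")))
})

test_that("class-proportion comparison matches exact hypergeometric enumeration", {
  eq <- compare_class_proportions(c(high_NKE = 5, other = 5),
                                  c(high_NKE = 5, other = 5))
  expect_true(all(eq$p == 1))
  expect_true(all(abs(eq$odds_ratio - 1) < 1e-9 | is.na(eq$odds_ratio)))
  # total separation: p = 2 / choose(20, 10)
  sep <- compare_class_proportions(c(high_NKE = 10, other = 0),
                                   c(high_NKE = 0, other = 10))
  expect_equal(sep$p[sep$class == "high_NKE"], 2 / choose(20, 10),
               tolerance = 1e-10)
  # swapping conditions inverts the odds ratio, preserves p
  a <- c(high_NKE = 7, other = 3)
  b <- c(high_NKE = 2, other = 8)
  ab <- compare_class_proportions(a, b)
  ba <- compare_class_proportions(b, a)
  expect_equal(ab$p, ba$p)
  expect_equal(ab$odds_ratio[1] * ba$odds_ratio[1], 1, tolerance = 1e-6)
})

test_that("motif-count filter keeps peaks at or above the threshold", {
  u <- simulate_peak_universe(n_shared = 20, n_lost = 0, n_gained = 0,
                              peak_width = 300, seed = 55,
                              planted_motifs = list(
                                list(kmer = "CTGACCTGC", fraction = 0.5,
                                     copies = 3)))
  keep3 <- filter_peaks_by_motif_count(u$wt, u$sequences, "CTGACCTGC",
                                       min_count = 3)
  counts <- attr(keep3, "motif_count")
  expect_true(all(counts[names(keep3$gr)] >= 3))
  expect_true(all(counts[setdiff(names(u$wt$gr), names(keep3$gr))] < 3))
  # peaks carrying only 2 copies are dropped at min_count = 3
  u2 <- simulate_peak_universe(n_shared = 5, n_lost = 0, n_gained = 0,
                               peak_width = 300, seed = 56,
                               planted_motifs = list(
                                 list(kmer = "CTGACCTGC", fraction = 1,
                                      copies = 2)))
  expect_equal(length(filter_peaks_by_motif_count(u2$wt, u2$sequences,
                                                  "CTGACCTGC", 3)), 0)
  expect_equal(length(filter_peaks_by_motif_count(u2$wt, u2$sequences,
                                                  "CTGACCTGC", 2)), 5)
  expect_error(filter_peaks_by_motif_count(u2$wt, u2$sequences[-1],
                                           "CTGACCTGC"),
               "no sequence")
})

test_that("dinucleotide shuffles preserve dinucleotide counts", {
  dinucs <- function(s) {
    ch <- strsplit(s, "")[[1]]
    sort(paste0(ch[-length(ch)], ch[-1]))
  }
  set.seed(2)
  for (i in 1:5) {
    s <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE),
               collapse = "")
    sh <- tfscope:::dinuc_shuffle_one(s)
    expect_equal(dinucs(sh), dinucs(s))
    expect_equal(substr(sh, 1, 1), substr(s, 1, 1))
  }
})

test_that("enrichment Z is deterministic and detects planted motifs", {
  u <- simulate_peak_universe(n_shared = 120, n_lost = 0, n_gained = 0,
                              peak_width = 120, seed = 60,
                              planted_motifs = list(
                                list(kmer = "CACTTCC", fraction = 0.5,
                                     copies = 1)))
  seqs <- u$sequences
  z1 <- enrichment_z(seqs, "CACTTCC", n_perm = 120, seed = 4)
  z2 <- enrichment_z(seqs, "CACTTCC", n_perm = 120, seed = 4)
  expect_identical(as.numeric(z1), as.numeric(z2))
  expect_gt(as.numeric(z1), 3)
  # absent motif can never be enriched
  expect_warning(
    z0 <- enrichment_z(u$sequences[1:20], "GGGGCCCCGG", n_perm = 100,
                       seed = 5),
    "degenerate")
  expect_lte(as.numeric(z0), 0)
})
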