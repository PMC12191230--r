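test_that("jaccard matches identity and hand-computed overlap", {
  a <- peak_set("chr1", c(0, 500), c(100, 700))
  expect_equal(jaccard(a, a), 1.0)
  x <- peak_set("chr1", 0, 100)
  y <- peak_set("chr1", 50, 150)
  expect_equal(jaccard(x, y), 50 / 150)
  expect_error(jaccard(peak_set(character(0), integer(0), integer(0)),
                       peak_set(character(0), integer(0), integer(0))),
               "empty")
})

test_that("jaccard equals the per-base-pair oracle on random sets", {
  set.seed(101)
  for (i in 1:25) {
    da <- random_intervals(sample(3:20, 1))
    db <- random_intervals(sample(3:20, 1))
    a <- peak_set(da$chrom, da$start, da$end, "a")
    b <- peak_set(db$chrom, db$start, db$end, "b")
    expect_equal(jaccard(a, b), oracle_jaccard(da, db))
    expect_equal(jaccard(a, b), jaccard(b, a))
  }
})

test_that("jaccard_matrix is symmetric, self-consistent, and flags empties", {
  set.seed(7)
  sets <- lapply(1:4, function(i) {
    d <- random_intervals(8)
    peak_set(d$chrom, d$start, d$end, paste0("allele", i))
  })
  m <- jaccard_matrix(sets)
  expect_equal(m, t(m))
  expect_true(all(diag(m) == 1))
  for (i in 1:4) for (j in 1:4) {
    expect_equal(m[i, j], jaccard(sets[[i]], sets[[j]]))
  }
  # identical sets -> all 1; disjoint sets -> 0 off-diagonal
  s <- sets[[1]]
  m1 <- jaccard_matrix(list(s, s, s))
  expect_true(all(m1 == 1))
  d1 <- peak_set("chr1", 0, 100, "d1")
  d2 <- peak_set("chr1", 200, 300, "d2")
  expect_equal(jaccard_matrix(list(d1, d2))[1, 2], 0)
  # empty set flagged as NA, not 0
  e <- peak_set(character(0), integer(0), integer(0), "empty")
  me <- jaccard_matrix(list(s, e))
  expect_true(is.na(me[1, 2]))
  expect_true(attr(me, "empty")[["empty"]])
})

test_that("classify_targets partitions constructed cases correctly", {
  wt <- peak_set("chr1", c(100, 300, 500), c(200, 400, 600), "WT",
                 name = c("p1", "p2", "p3"))
  var <- peak_set("chr1", c(350, 800), c(450, 900), "V")
  p <- classify_targets(wt, var)
  expect_equal(sort(names(p$a_peaks$gr)), c("p1", "p3"))
  expect_equal(names(p$b_peaks$gr), "p2")
  expect_equal(length(p$c_peaks), 1)
  # WT-side A and B tile WT exactly
  expect_equal(length(p$a_peaks) + length(p$b_peaks), length(wt))
  # variant = WT -> everything retained
  p2 <- classify_targets(wt, peak_set("chr1", c(100, 300, 500),
                                      c(200, 400, 600), "V"))
  expect_equal(length(p2$a_peaks), 0)
  expect_equal(length(p2$c_peaks), 0)
  expect_equal(length(p2$b_peaks), 3)
  expect_error(classify_targets(wt, var, min_overlap_bp = 0), "min_overlap")
})

test_that("classify_targets respects the minimum-overlap parameter", {
  wt <- peak_set("chr1", 100, 200, "WT")
  var <- peak_set("chr1", 195, 300, "V")  # 5 bp overlap
  expect_equal(length(classify_targets(wt, var, 5)$b_peaks), 1)
  expect_equal(length(classify_targets(wt, var, 6)$b_peaks), 0)
})

test_that("classification recovers planted truth and ignores input order", {
  u <- simulate_peak_universe(n_shared = 25, n_lost = 12, n_gained = 8,
                              n_chrom = 2, seed = 77)
  p <- classify_targets(u$wt, u$variant)
  lab <- setNames(u$truth$label, u$truth$name)
  expect_true(all(lab[names(p$a_peaks$gr)] == "lost"))
  expect_true(all(lab[names(p$b_peaks$gr)] == "shared"))
  expect_true(all(lab[names(p$c_peaks$gr)] == "gained"))
  expect_equal(length(p$a_peaks), 12)
  expect_equal(length(p$b_peaks), 25)
  expect_equal(length(p$c_peaks), 8)
})

test_that("assign_genes applies the basal-plus-extension rule", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", tss = 10000,
                      strand = "+", stringsAsFactors = FALSE)
  pk <- peak_set("chr1", 3900, 4100, name = "pk")  # midpoint 4000
  asn <- assign_genes(pk, genes)
  expect_equal(asn[["pk"]], "g1")  # inside [3500, 12500) basal
  # midpoint 200 kb away: beyond the 100 kb extension cap
  far <- peak_set("chr1", 209900, 210100, name = "far")
  expect_equal(length(assign_genes(far, genes)[["far"]]), 0)
  # just inside the extension
  near <- peak_set("chr1", 100000, 100200, name = "near")  # midpoint 100100
  expect_equal(assign_genes(near, genes)[["near"]], "g1")
  # unknown chromosome -> warning, gene skipped
  g2 <- rbind(genes, data.frame(gene_id = "g2", chrom = "chrX", tss = 5,
                                strand = "+"))
  expect_warning(asn2 <- assign_genes(pk, g2), "skipped")
  expect_equal(asn2[["pk"]], "g1")
})

test_that("gene domains match the per-bp oracle, including shared extensions", {
  # two + strand genes 40 kb apart on a 60 kb toy chromosome
  genes <- data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                      tss = c(10000, 50000), strand = c("+", "-"),
                      stringsAsFactors = FALSE)
  genome_len <- 60000
  member <- oracle_domain_membership(genes, genome_len)
  mids <- seq(0, genome_len - 1, by = 997)
  pk <- peak_set(rep("chr1", length(mids)), mids, mids + 2,
                 name = paste0("m", mids))
  asn <- assign_genes(pk, genes)
  for (k in seq_along(mids)) {
    mid <- floor((mids[k] + mids[k] + 2) / 2)
    expected <- genes$gene_id[member[, mid + 1]]
    expect_setequal(asn[[paste0("m", mids[k])]], expected)
  }
  # every bp belongs to at most two domains under this rule
  expect_true(all(colSums(member) <= 2))
})

test_that("partition_gene_sets unions gene assignments per subset", {
  u <- simulate_peak_universe(n_shared = 5, n_lost = 3, n_gained = 2,
                              seed = 9)
  p <- classify_targets(u$wt, u$variant)
  # one gene per planted peak, TSS at the peak midpoint
  genes <- data.frame(gene_id = paste0("gene_", u$truth$name),
                      chrom = u$truth$chrom,
                      tss = floor((u$truth$start + u$truth$end) / 2),
                      strand = "+", stringsAsFactors = FALSE)
  asn <- c(assign_genes(u$wt, genes, max_ext = 0),
           assign_genes(u$variant, genes, max_ext = 0))
  p <- partition_gene_sets(p, asn)
  expect_true(all(paste0("gene_", names(p$a_peaks$gr)) %in% p$a_genes))
  expect_true(all(paste0("gene_", names(p$c_peaks$gr)) %in% p$c_genes))
  # all peaks unassigned -> empty gene sets
  p0 <- partition_gene_sets(classify_targets(u$wt, u$variant),
                            list())
  expect_equal(length(p0$a_genes), 0)
  expect_equal(length(p0$b_genes), 0)
})

test_that("BED round trip preserves a peak set", {
  d <- random_intervals(10)
  ps <- peak_set(d$chrom, d$start, d$end, "WT")
  path <- tempfile(fileext = ".bed")
  write_peaks_bed(ps, path)
  back <- read_peaks_bed(path, "WT")
  expect_equal(as.data.frame(back), as.data.frame(ps))
})
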