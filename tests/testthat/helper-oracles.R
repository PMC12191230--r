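# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's interval/rank machinery: booleans per base pair,
# O(n^2) pair counting, naive sliding windows.

# per-base-pair Jaccard on a toy genome: mark occupancy arrays and count
oracle_jaccard <- function(df_a, df_b, genome_len = 10000,
                           chroms = c("chr1", "chr2")) {
  occ <- function(df) {
    m <- matrix(FALSE, length(chroms), genome_len,
                dimnames = list(chroms, NULL))
    for (i in seq_len(nrow(df))) {
      m[df$chrom[i], (df$start[i] + 1):df$end[i]] <- TRUE
    }
    m
  }
  a <- occ(df_a); b <- occ(df_b)
  inter <- sum(a & b); uni <- sum(a | b)
  inter / uni
}

# random interval set as a BED-style data.frame (possibly overlapping;
# peak_set() merges)
random_intervals <- function(n, genome_len = 10000,
                             chroms = c("chr1", "chr2"), max_w = 400) {
  w <- sample.int(max_w, n, replace = TRUE)
  s <- vapply(w, function(wi) sample.int(genome_len - wi, 1), integer(1))
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = s, end = s + w, stringsAsFactors = FALSE)
}

# naive sliding-window k-mer scan (both strands), counting overlaps
oracle_scan_count <- function(seq, kmer) {
  rc <- chartr("ACGT", "TGCA",
               paste(rev(strsplit(kmer, "")[[1]]), collapse = ""))
  count_pat <- function(pat) {
    k <- nchar(pat)
    n <- 0L
    for (i in seq_len(nchar(seq) - k + 1)) {
      if (substr(seq, i, i + k - 1) == pat) n <- n + 1L
    }
    n
  }
  count_pat(kmer) + count_pat(rc)
}

# O(n^2) pair-counting E-score oracle
oracle_escore <- function(probes, kmer8) {
  rc <- chartr("ACGT", "TGCA",
               paste(rev(strsplit(kmer8, "")[[1]]), collapse = ""))
  fg <- grepl(kmer8, probes$sequence, fixed = TRUE) |
    grepl(rc, probes$sequence, fixed = TRUE)
  if (!any(fg)) return(NA_real_)
  top_half <- function(v) sort(v, decreasing = TRUE)[seq_len(ceiling(length(v) / 2))]
  f <- top_half(probes$intensity[fg])
  b <- top_half(probes$intensity[!fg])
  U <- 0
  for (fi in f) for (bi in b) {
    U <- U + if (fi > bi) 1 else if (fi == bi) 0.5 else 0
  }
  U / (length(f) * length(b)) - 0.5
}

# per-bp regulatory-domain oracle: for every bp and gene, membership under
# the basal-plus-extension rule stated positionally (extension occupied iff
# within max_ext of the TSS and no other basal domain intersects the span
# between the bp and this gene's basal edge)
oracle_domain_membership <- function(genes, genome_len,
                                     basal_up = 6500, basal_down = 2500,
                                     max_ext = 100000) {
  plus <- genes$strand == "+"
  bs <- pmax(ifelse(plus, genes$tss - basal_up, genes$tss - basal_down), 0)
  be <- ifelse(plus, genes$tss + basal_down, genes$tss + basal_up)
  n <- nrow(genes)
  member <- matrix(FALSE, n, genome_len)
  basal_occ <- function(j, lo, hi) {
    # does gene j's basal domain intersect [lo, hi) ?
    bs[j] < hi && be[j] > lo
  }
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    others <- others[genes$chrom[others] == genes$chrom[i]]
    for (p in 0:(genome_len - 1)) {
      inside <- FALSE
      if (p >= bs[i] && p < be[i]) {
        inside <- TRUE
      } else if (p < bs[i] && p >= genes$tss[i] - max_ext) {
        inside <- !any(vapply(others, basal_occ, logical(1),
                              lo = p, hi = bs[i]))
      } else if (p >= be[i] && p < genes$tss[i] + max_ext) {
        inside <- !any(vapply(others, basal_occ, logical(1),
                              lo = be[i], hi = p + 1))
      }
      member[i, p + 1] <- inside
    }
  }
  member
}

# straight-line and zigzag toy trajectories
straight_track <- function(n = 10, step = 0.2, dt = 0.02) {
  data.frame(frame = seq_len(n), x = step * seq_len(n), y = 0)
}
zigzag_track <- function(n = 10, step = 0.2) {
  data.frame(frame = seq_len(n), x = step * (seq_len(n) %% 2), y = 0)
}
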