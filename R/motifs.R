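#' Scan a sequence for exact k-mer matches on both strands
#'
#' Finds every exact occurrence of `kmer` on the forward strand and of its
#' reverse complement (a reverse-strand site read on the forward sequence).
#' Overlapping matches are counted; `N` never matches.
#'
#' @param sequence a single DNA string over `{A,C,G,T,N}`.
#' @param kmer the motif core (length >= 4 recommended).
#' @return data.frame (`offset` 1-based, `strand` `"+"`/`"-"`). A
#'   palindromic k-mer reports each position once per strand.
#' @export
scan_kmer <- function(sequence, kmer) {
  stopifnot(length(sequence) == 1, nchar(kmer) >= 1)
  sequence <- toupper(sequence)
  kmer <- toupper(kmer)
  find_all <- function(pat) {
    hits <- integer(0)
    from <- 1L
    repeat {
      p <- regexpr(pat, substr(sequence, from, nchar(sequence)),
                   fixed = TRUE)
      if (p == -1L) break
      hits <- c(hits, from + as.integer(p) - 1L)
      from <- from + as.integer(p)  # advance one base: overlapping matches
    }
    hits
  }
  fwd <- find_all(kmer)
  rc <- revcomp(kmer)
  rev <- find_all(rc)
  if (kmer == rc) rev <- fwd  # palindrome: same positions, opposite strand
  data.frame(
    offset = c(fwd, rev),
    strand = rep(c("+", "-"), c(length(fwd), length(rev))),
    stringsAsFactors = FALSE
  )
}

#' Count k-mer occurrences (both strands) per sequence
#' @param sequences character vector of DNA sequences.
#' @param kmer motif core.
#' @return Integer vector of per-sequence occurrence counts.
#' @export
count_kmer <- function(sequences, kmer) {
  vapply(sequences, function(s) nrow(scan_kmer(s, kmer)), integer(1),
         USE.NAMES = FALSE)
}

#' Tally the immediate flanking bases around a core motif
#'
#' For every occurrence of the core on either strand, reads the immediate
#' 5' and 3' base on the strand of the match (for a reverse-strand match
#' the 5' flank is the complement of the base after the site on the
#' forward strand). Occurrences at a sequence edge contribute only the
#' flank they have.
#'
#' @param sequences character vector of DNA sequences.
#' @param core the core motif (default the NKE core `CACTT`).
#' @return 4x2 integer matrix: rows A/C/G/T, columns `five_prime` /
#'   `three_prime`; each column sums to the number of occurrences with
#'   that flank defined.
#' @export
flank_preference <- function(sequences, core = "CACTT") {
  bases <- c("A", "C", "G", "T")
  counts <- matrix(0L, 4, 2,
                   dimnames = list(bases, c("five_prime", "three_prime")))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  k <- nchar(core)
  total <- 0L
  for (s in sequences) {
    s <- toupper(s)
    occ <- scan_kmer(s, core)
    total <- total + nrow(occ)
    for (i in seq_len(nrow(occ))) {
      off <- occ$offset[i]
      before <- if (off > 1) substr(s, off - 1, off - 1) else NA
      after <- if (off + k <= nchar(s)) substr(s, off + k, off + k) else NA
      if (occ$strand[i] == "+") {
        five <- before; three <- after
      } else {
        five <- if (!is.na(after)) comp[[after]] else NA
        three <- if (!is.na(before)) comp[[before]] else NA
      }
      if (!is.na(five) && five %in% bases) {
        counts[five, "five_prime"] <- counts[five, "five_prime"] + 1L
      }
      if (!is.na(three) && three %in% bases) {
        counts[three, "three_prime"] <- counts[three, "three_prime"] + 1L
      }
    }
  }
  if (total == 0) stop("core motif has no occurrence in the sequences")
  counts
}

#' Assign an 8-mer to a binding-site class
#'
#' Classes follow the three clusters seen in comparative E-score
#' landscapes: `high_NKE` if the 8-mer contains the high-affinity flanked
#' core `CCACTT` on either strand; else `low_NKE` if it contains the core
#' `CACTT`; else `HOX_like` if it contains the homeodomain core `TAAT`;
#' else `other`. The precedence (high > low > HOX > other) resolves 8-mers
#' containing several cores; the substring rule is a documented proxy for
#' cluster membership.
#'
#' @param kmer8 character vector of 8-mers over `{A,C,G,T}`.
#' @return Character vector of class labels; strand-invariant.
#' @export
assign_motif_class <- function(kmer8) {
  stopifnot(all(nchar(kmer8) == 8))
  up <- toupper(kmer8)
  rc <- revcomp(up)
  has <- function(pat) {
    grepl(pat, up, fixed = TRUE) | grepl(pat, rc, fixed = TRUE)
  }
  out <- rep("other", length(up))
  out[has("TAAT")] <- "HOX_like"
  out[has("CACTT")] <- "low_NKE"
  out[has("CCACTT")] <- "high_NKE"
  out
}

#' Compare per-class motif counts between two conditions
#'
#' For each class, builds the 2x2 table (class vs rest, condition a vs b)
#' and reports the odds ratio and two-sided Fisher exact p-value.
#'
#' @param counts_a,counts_b named non-negative integer vectors of per-class
#'   counts (same class names).
#' @return data.frame (`class`, `a`, `b`, `odds_ratio`, `p`); `p` is `NA`
#'   where both margins of the table are zero.
#' @export
compare_class_proportions <- function(counts_a, counts_b) {
  classes <- union(names(counts_a), names(counts_b))
  a <- stats::setNames(rep(0L, length(classes)), classes)
  b <- a
  a[names(counts_a)] <- as.integer(counts_a)
  b[names(counts_b)] <- as.integer(counts_b)
  if (any(a < 0) || any(b < 0)) stop("counts must be non-negative")
  res <- lapply(classes, function(cl) {
    tab <- matrix(c(a[[cl]], sum(a) - a[[cl]],
                    b[[cl]], sum(b) - b[[cl]]), 2, 2)
    if (sum(tab) == 0) {
      return(data.frame(class = cl, a = a[[cl]], b = b[[cl]],
                        odds_ratio = NA_real_, p = NA_real_))
    }
    ft <- stats::fisher.test(tab)
    data.frame(class = cl, a = a[[cl]], b = b[[cl]],
               odds_ratio = unname(ft$estimate), p = ft$p.value)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Filter peaks by motif occurrence count
#'
#' Retains peaks whose sequence carries at least `min_count` occurrences of
#' the motif on either strand — e.g. the "three or more HAND1 motifs"
#' filter used to isolate putative co-bound targets.
#'
#' @param peaks a `peak_set`.
#' @param sequences named character vector keyed by peak name.
#' @param kmer motif core.
#' @param min_count minimum occurrences (default 3).
#' @return The filtered `peak_set`; counts attached as attribute
#'   `motif_count`.
#' @export
filter_peaks_by_motif_count <- function(peaks, sequences, kmer,
                                        min_count = 3) {
  stopifnot(inherits(peaks, "peak_set"))
  nm <- names(peaks$gr)
  missing_seq <- setdiff(nm, names(sequences))
  if (length(missing_seq)) {
    stop("no sequence for peak(s): ",
         paste(utils::head(missing_seq, 5), collapse = ", "))
  }
  counts <- count_kmer(sequences[nm], kmer)
  keep <- counts >= min_count
  out <- peak_set_from_granges(peaks$gr[keep], peaks$allele)
  attr(out, "motif_count") <- stats::setNames(counts, nm)
  out
}

# Altschul-Erickson dinucleotide-preserving shuffle of one sequence:
# random Eulerian path through the dinucleotide multigraph, so mono- and
# dinucleotide counts are conserved exactly.
dinuc_shuffle_one <- function(s) {
  chars <- strsplit(toupper(s), "")[[1]]
  n <- length(chars)
  if (n < 3) return(s)
  verts <- unique(chars)
  edges <- split(chars[-1], factor(chars[-n], levels = verts))
  last <- chars[n]
  for (attempt in 1:100) {
    # pick a random "last edge" for every vertex except the terminal one
    last_edge <- vapply(verts, function(v) {
      if (v == last || length(edges[[v]]) == 0) return(NA_character_)
      sample(edges[[v]], 1)
    }, character(1))
    # the chosen last edges must form a tree into `last`
    ok <- TRUE
    for (v in verts) {
      if (v == last || is.na(last_edge[[v]])) next
      seen <- character(0)
      cur <- v
      while (cur != last) {
        if (cur %in% seen || is.na(last_edge[[cur]])) { ok <- FALSE; break }
        seen <- c(seen, cur)
        cur <- last_edge[[cur]]
      }
      if (!ok) break
    }
    if (!ok) next
    # shuffle remaining edges, append the reserved last edge
    lists <- lapply(verts, function(v) {
      e <- edges[[v]]
      if (is.na(last_edge[[v]])) return(sample(e))
      i <- match(last_edge[[v]], e)
      c(sample(e[-i]), e[i])
    })
    names(lists) <- verts
    ptr <- stats::setNames(rep(1L, length(verts)), verts)
    out <- character(n)
    out[1] <- chars[1]
    cur <- chars[1]
    for (i in 2:n) {
      nxt <- lists[[cur]][ptr[[cur]]]
      ptr[[cur]] <- ptr[[cur]] + 1L
      out[i] <- nxt
      cur <- nxt
    }
    return(paste(out, collapse = ""))
  }
  stop("dinucleotide shuffle failed to find an Eulerian path")
}

#' Permutation Z-score for motif enrichment in peak sequences
#'
#' Compares the observed total motif count (both strands, all peaks)
#' against a null distribution built by dinucleotide-preserving shuffles of
#' each peak sequence. This permutation statistic stands in for exact
#' known-motif enrichment scores; it is a methodological substitution, not
#' a reimplementation of any published enrichment engine.
#'
#' @param sequences character vector of peak sequences.
#' @param kmer motif core.
#' @param n_perm number of shuffled replicates (>= 100).
#' @param seed integer seed (shuffles are seed-deterministic).
#' @return Z = (observed - mean_null) / sd_null, with the null draws in
#'   attribute `null`. If `sd_null` is 0 the Z is `+/-Inf` with a warning.
#' @export
enrichment_z <- function(sequences, kmer, n_perm = 1000, seed) {
  stopifnot(n_perm >= 100)
  obs <- sum(count_kmer(sequences, kmer))
  with_seed(seed, {
    null <- vapply(seq_len(n_perm), function(b) {
      sum(count_kmer(vapply(sequences, dinuc_shuffle_one, character(1)),
                     kmer))
    }, numeric(1))
    m <- mean(null)
    s <- stats::sd(null)
    if (s == 0) {
      warning("null distribution degenerate (sd = 0)")
      z <- if (obs > m) Inf else if (obs < m) -Inf else 0
    } else {
      z <- (obs - m) / s
    }
    structure(z, null = null, observed = obs)
  })
}
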