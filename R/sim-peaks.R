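random_dna <- function(n, len, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  vapply(seq_len(n), function(i) {
    paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
  }, character(1))
}

revcomp <- function(x) {
  chartr("ACGTacgt", "TGCAtgca", vapply(strsplit(x, ""), function(s) {
    paste(rev(s), collapse = "")
  }, character(1)))
}

# Place `counts[chrom]` non-overlapping width-w intervals uniformly on a
# chromosome of length L via the spacing construction (sample gaps, then
# stack widths), which cannot produce overlaps.
place_nonoverlapping <- function(n, L, w) {
  if (n == 0) return(integer(0))
  slack <- L - n * w
  if (slack < 0) stop("planted peaks cannot be placed without overlap: ",
                      "genome too small for ", n, " peaks of width ", w)
  starts <- sort(sample.int(slack + 1L, n, replace = TRUE) - 1L)
  starts + (seq_len(n) - 1L) * w
}

plant_motif <- function(seqs, kmer, fraction, copies) {
  n <- length(seqs)
  if (n == 0 || fraction <= 0 || copies <= 0) return(seqs)
  carriers <- which(stats::runif(n) < fraction)
  if (fraction >= 1) carriers <- seq_len(n)
  k <- nchar(kmer)
  for (i in carriers) {
    len <- nchar(seqs[i])
    # non-overlapping slots for the requested copies
    slots <- floor(len / k)
    if (slots < copies) stop("peak too short to plant ", copies,
                             " copies of ", kmer)
    chosen <- sort(sample.int(slots, copies))
    s <- seqs[i]
    for (slot in chosen) {
      ins <- if (stats::runif(1) < 0.5) kmer else revcomp(kmer)
      pos <- (slot - 1L) * k + 1L
      substr(s, pos, pos + k - 1L) <- ins
    }
    seqs[i] <- s
  }
  seqs
}

#' Simulate a WT/variant peak universe with planted structure
#'
#' Plants three classes of non-overlapping peaks on a synthetic genome:
#' shared peaks (bound by both alleles), lost peaks (WT-only) and gained
#' peaks (variant-only). The WT set is shared+lost, the variant set is
#' shared+gained. Peak sequences are random DNA at the requested GC content
#' with motifs planted into WT-bound (shared and lost) peaks; an optional
#' second motif list is planted into gained peaks to emulate a binding
#' specificity switch.
#'
#' @param n_shared,n_lost,n_gained planted peak counts per class.
#' @param genome_length bp per chromosome.
#' @param n_chrom number of chromosomes (`chr1..chrN`).
#' @param peak_width peak width in bp.
#' @param planted_motifs list of `list(kmer=, fraction=, copies=)` planted
#'   into shared and lost (WT) peaks, each copy on a random strand.
#' @param gained_motifs same structure, planted into gained peaks only.
#' @param gc_background background GC fraction.
#' @param seed integer seed (required; generators hold no global state).
#' @return List with `wt` and `variant` (`peak_set`), `sequences` (named
#'   character vector keyed by peak name) and `truth` (data.frame with
#'   `name`, `chrom`, `start`, `end`, `label` in
#'   `{shared, lost, gained}`).
#' @export
simulate_peak_universe <- function(n_shared = 10, n_lost = 5, n_gained = 3,
                                   genome_length = 1e6, n_chrom = 1,
                                   peak_width = 500,
                                   planted_motifs = list(),
                                   gained_motifs = list(),
                                   gc_background = 0.5, seed) {
  stopifnot(n_shared >= 0, n_lost >= 0, n_gained >= 0, peak_width > 0)
  with_seed(seed, {
    n_total <- n_shared + n_lost + n_gained
    chrom_of <- sort(sample.int(n_chrom, n_total, replace = TRUE))
    starts <- integer(n_total)
    for (cc in unique(chrom_of)) {
      idx <- which(chrom_of == cc)
      # width + 1 keeps at least 1 bp between peaks so no two planted
      # peaks are bookended (bookended intervals would merge in peak_set)
      starts[idx] <- place_nonoverlapping(length(idx), genome_length - 1L,
                                          peak_width + 1L)
    }
    labels <- sample(rep(c("shared", "lost", "gained"),
                         c(n_shared, n_lost, n_gained)))
    truth <- data.frame(
      chrom = paste0("chr", chrom_of),
      start = starts,
      end = starts + peak_width,
      label = labels,
      stringsAsFactors = FALSE
    )
    truth <- truth[order(chrom_of, truth$start), , drop = FALSE]
    truth$name <- sprintf("peak_%04d_%s", seq_len(n_total), truth$label)
    rownames(truth) <- NULL

    seqs <- random_dna(n_total, peak_width, gc_background)
    names(seqs) <- truth$name
    wt_idx <- truth$label %in% c("shared", "lost")
    for (m in planted_motifs) {
      seqs[wt_idx] <- plant_motif(seqs[wt_idx], m$kmer,
                                  m$fraction %||% 1, m$copies %||% 1)
    }
    gained_idx <- truth$label == "gained"
    for (m in gained_motifs) {
      seqs[gained_idx] <- plant_motif(seqs[gained_idx], m$kmer,
                                      m$fraction %||% 1, m$copies %||% 1)
    }

    make_set <- function(keep, allele) {
      tr <- truth[keep, , drop = FALSE]
      peak_set(tr$chrom, tr$start, tr$end, allele = allele, name = tr$name)
    }
    list(
      wt = make_set(truth$label %in% c("shared", "lost"), "WT"),
      variant = make_set(truth$label %in% c("shared", "gained"), "variant"),
      sequences = seqs,
      truth = truth[, c("name", "chrom", "start", "end", "label")]
    )
  })
}

#' Write named sequences to FASTA
#' @param seqs named character vector of DNA sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  dna <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(dna, path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#' @param path FASTA path.
#' @return Named character vector.
#' @export
read_fasta <- function(path) {
  dna <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(dna), names(dna))
}
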