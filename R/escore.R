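#' Collapse an 8-mer to its reverse-complement-canonical form
#' @param kmer8 character vector of 8-mers.
#' @return The lexicographically smaller of each 8-mer and its reverse
#'   complement.
#' @export
collapse_kmer <- function(kmer8) {
  rc <- revcomp(toupper(kmer8))
  up <- toupper(kmer8)
  ifelse(up <= rc, up, rc)
}

# probes whose sequence contains the 8-mer on either strand
kmer_foreground <- function(sequences, kmer8) {
  grepl(kmer8, sequences, fixed = TRUE) |
    grepl(revcomp(kmer8), sequences, fixed = TRUE)
}

#' Rank-based E-score of one 8-mer from PBM probe intensities
#'
#' The E-score is a rank statistic comparing probes that contain the 8-mer
#' (foreground, either strand) against all others (background). Within
#' each group the top half by intensity (`ceiling(n/2)` probes) is kept;
#' E = U / (n_f * n_b) - 0.5, where U counts (foreground, background)
#' pairs with the foreground probe brighter (ties credit 1/2). Bounded in
#' \[-0.5, 0.5\]; +0.5 means perfect separation above background. Being
#' rank-based, E is invariant to any strictly monotone transform of the
#' intensities. Probes containing `N` are excluded.
#'
#' @param probes data.frame with columns `sequence`, `intensity`.
#' @param kmer8 the 8-mer to score.
#' @return E in \[-0.5, 0.5\]; `NA` if the 8-mer occurs in no probe.
#'   Attribute `n_fg` is the foreground probe count before halving.
#' @export
escore <- function(probes, kmer8) {
  stopifnot(nchar(kmer8) == 8)
  ok <- !grepl("N", probes$sequence, fixed = TRUE)
  seqs <- probes$sequence[ok]
  ints <- probes$intensity[ok]
  fg <- kmer_foreground(seqs, toupper(kmer8))
  n_fg_total <- sum(fg)
  if (n_fg_total == 0) return(structure(NA_real_, n_fg = 0L))
  if (n_fg_total < 2 || sum(!fg) < 2) {
    # still computable, but flag tiny groups via the n_fg attribute
  }
  top_half <- function(v) {
    k <- ceiling(length(v) / 2)
    sort(v, decreasing = TRUE)[seq_len(k)]
  }
  f <- top_half(ints[fg])
  b <- top_half(ints[!fg])
  r <- rank(c(f, b))  # average rank on ties = half credit per tied pair
  U <- sum(r[seq_along(f)]) - length(f) * (length(f) + 1) / 2
  structure(U / (length(f) * length(b)) - 0.5, n_fg = n_fg_total)
}

#' E-scores for every 8-mer present in a probe table
#'
#' Computes the E-score of every reverse-complement-collapsed 8-mer that
#' occurs in at least one probe. Uses a single global intensity ordering
#' and per-8-mer rank walks, exact (and equal to [escore()]) when
#' intensities are untied; with tied intensities it falls back to the
#' per-8-mer rank method.
#'
#' @param probes data.frame with columns `probe_id`, `sequence`,
#'   `intensity` (equal-length sequences).
#' @return data.frame (`kmer`, `escore`, `n_fg`) with one row per collapsed
#'   8-mer, `kmer` the lexicographically smaller of the pair.
#' @export
escore_table <- function(probes) {
  ok <- !grepl("N", probes$sequence, fixed = TRUE)
  seqs <- toupper(probes$sequence[ok])
  ints <- probes$intensity[ok]
  n <- length(seqs)
  L <- unique(nchar(seqs))
  stopifnot(length(L) == 1, L >= 8)

  # enumerate collapsed 8-mers per probe (forward + reverse complement)
  n_off <- L - 8 + 1
  rcs <- chartr("ACGT", "TGCA", vapply(strsplit(seqs, ""), function(s) {
    paste(rev(s), collapse = "")
  }, character(1)))
  kmer_cols <- vector("list", n_off)
  for (k in seq_len(n_off)) {
    fwd <- substr(seqs, k, k + 7)
    # 8-mer at forward offset k pairs with the rc 8-mer at mirrored offset
    rev <- substr(rcs, L - 8 - k + 2, L - k + 1)
    kmer_cols[[k]] <- ifelse(fwd <= rev, fwd, rev)
  }
  probe_idx <- rep(seq_len(n), n_off)
  kmers <- unlist(kmer_cols, use.names = FALSE)
  dup <- duplicated(paste(probe_idx, kmers))
  probe_idx <- probe_idx[!dup]
  kmers <- kmers[!dup]
  by_kmer <- split(probe_idx, kmers)

  ord <- order(ints, decreasing = TRUE)
  pos_of <- integer(n)
  pos_of[ord] <- seq_len(n)  # global intensity rank, 1 = brightest
  tied <- anyDuplicated(ints) > 0

  out_k <- names(by_kmer)
  out_e <- numeric(length(out_k))
  out_n <- integer(length(out_k))
  for (i in seq_along(out_k)) {
    fg_idx <- by_kmer[[i]]
    nf <- length(fg_idx)
    out_n[i] <- nf
    if (tied) {
      fgl <- logical(n)
      fgl[fg_idx] <- TRUE
      f <- sort(ints[fgl], decreasing = TRUE)
      f <- f[seq_len(ceiling(nf / 2))]
      b <- sort(ints[!fgl], decreasing = TRUE)
      b <- b[seq_len(ceiling((n - nf) / 2))]
      r <- rank(c(f, b))
      U <- sum(r[seq_along(f)]) - length(f) * (length(f) + 1) / 2
      out_e[i] <- U / (length(f) * length(b)) - 0.5
      next
    }
    p <- sort(pos_of[fg_idx])          # global positions of fg, ascending
    kf <- ceiling(nf / 2)
    nb <- n - nf
    kb <- ceiling(nb / 2)
    pf <- p[seq_len(kf)]               # kept foreground (brightest half)
    bg_above <- pf - seq_len(kf)       # background probes brighter than each
    U <- sum(pmax(0, kb - pmin(bg_above, kb)))
    out_e[i] <- U / (kf * kb) - 0.5
  }
  data.frame(kmer = out_k, escore = out_e, n_fg = out_n,
             stringsAsFactors = FALSE)
}

#' Compare WT and variant E-score landscapes
#'
#' Summarises two E-score tables from the same probe design: counts of
#' significantly bound 8-mers (E above `cutoff`) per allele, their
#' motif-class proportions (via [assign_motif_class()]), shared/unique
#' significant 8-mers, and the (E_wt, E_var) scatter pairs over shared
#' keys.
#'
#' @param wt,var E-score tables from [escore_table()].
#' @param cutoff significance cutoff on E (default 0.35, the conventional
#'   threshold at FDR < 0.01 on universal arrays).
#' @return List: `n_significant` (named counts), `class_counts` (matrix
#'   class x allele over significant 8-mers), `shared_significant`,
#'   `unique_wt`, `unique_var` (character vectors), and `pairs`
#'   (data.frame `kmer`, `e_wt`, `e_var` over shared keys).
#' @export
compare_landscapes <- function(wt, var, cutoff = 0.35) {
  shared_keys <- intersect(wt$kmer, var$kmer)
  if (length(shared_keys) == 0) {
    stop("E-score tables share no 8-mers: probe designs do not match")
  }
  sig_wt <- wt$kmer[!is.na(wt$escore) & wt$escore > cutoff]
  sig_var <- var$kmer[!is.na(var$escore) & var$escore > cutoff]
  classes <- c("high_NKE", "low_NKE", "HOX_like", "other")
  class_count <- function(kmers) {
    tab <- table(factor(assign_motif_class(kmers), levels = classes))
    as.integer(tab)
  }
  cc <- cbind(wt = class_count(sig_wt), var = class_count(sig_var))
  rownames(cc) <- classes
  ew <- stats::setNames(wt$escore, wt$kmer)
  ev <- stats::setNames(var$escore, var$kmer)
  list(
    n_significant = c(wt = length(sig_wt), var = length(sig_var)),
    class_counts = cc,
    shared_significant = intersect(sig_wt, sig_var),
    unique_wt = setdiff(sig_wt, sig_var),
    unique_var = setdiff(sig_var, sig_wt),
    pairs = data.frame(kmer = shared_keys,
                       e_wt = unname(ew[shared_keys]),
                       e_var = unname(ev[shared_keys]),
                       stringsAsFactors = FALSE)
  )
}
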