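#' Jaccard similarity between two peak sets
#'
#' The Jaccard index of two interval sets is the number of base pairs in
#' their intersection divided by the number of base pairs in their union —
#' a scale-independent measure of how much genomic occupancy two binding
#' profiles share.
#'
#' @param a,b `peak_set` objects (merged and sorted by construction).
#' @return A single number in \[0, 1\].
#' @export
jaccard <- function(a, b) {
  stopifnot(inherits(a, "peak_set"), inherits(b, "peak_set"))
  if (length(a) == 0 && length(b) == 0) {
    stop("jaccard undefined: both peak sets are empty")
  }
  inter <- sum(GenomicRanges::width(GenomicRanges::intersect(a$gr, b$gr)))
  uni <- total_bp(a) + total_bp(b) - inter
  inter / uni
}

#' Pairwise Jaccard matrix over peak sets
#'
#' Assembles all pairwise Jaccard indices into a symmetric matrix ready for
#' hierarchical clustering. Rows/columns of empty sets are `NA` and flagged
#' in the `"empty"` attribute rather than silently reported as 0.
#'
#' @param sets list of `peak_set` objects (at least 2).
#' @return Symmetric numeric matrix with allele labels as dimnames;
#'   attribute `"empty"` is a logical vector marking empty input sets.
#' @export
jaccard_matrix <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2)
  labels <- vapply(sets, function(s) s$allele, character(1))
  n <- length(sets)
  m <- matrix(NA_real_, n, n, dimnames = list(labels, labels))
  empty <- vapply(sets, function(s) length(s) == 0, logical(1))
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (empty[i] || empty[j]) next
      v <- jaccard(sets[[i]], sets[[j]])
      m[i, j] <- v
      m[j, i] <- v
    }
  }
  attr(m, "empty") <- stats::setNames(empty, labels)
  m
}

#' Partition WT and variant peaks into A/B/C target sets
#'
#' A-set: peaks bound exclusively by WT (targets lost by the variant).
#' B-set: WT peaks also bound by the variant (retained targets; the
#' variant-side overlapping peaks are kept alongside as `b_peaks_variant`).
#' C-set: peaks bound uniquely by the variant (off-target gains).
#'
#' @param wt,variant `peak_set` objects.
#' @param min_overlap_bp minimum overlap (bp) for a WT and a variant peak to
#'   count as the same target. Default 1.
#' @return A `target_partition` with `a_peaks`, `b_peaks`, `c_peaks`,
#'   `b_peaks_variant` and (after [partition_gene_sets()]) gene-id sets.
#' @export
classify_targets <- function(wt, variant, min_overlap_bp = 1L) {
  stopifnot(inherits(wt, "peak_set"), inherits(variant, "peak_set"))
  if (min_overlap_bp < 1) stop("min_overlap_bp must be >= 1")
  hits_wt <- GenomicRanges::findOverlaps(wt$gr, variant$gr,
                                         minoverlap = as.integer(min_overlap_bp))
  wt_has <- seq_along(wt$gr) %in% S4Vectors::queryHits(hits_wt)
  var_has <- seq_along(variant$gr) %in% S4Vectors::subjectHits(hits_wt)
  part <- list(
    a_peaks = peak_set_from_granges(wt$gr[!wt_has], wt$allele),
    b_peaks = peak_set_from_granges(wt$gr[wt_has], wt$allele),
    b_peaks_variant = peak_set_from_granges(variant$gr[var_has],
                                            variant$allele),
    c_peaks = peak_set_from_granges(variant$gr[!var_has], variant$allele),
    a_genes = character(0), b_genes = character(0), c_genes = character(0),
    min_overlap_bp = as.integer(min_overlap_bp)
  )
  structure(part, class = "target_partition")
}

#' @export
print.target_partition <- function(x, ...) {
  cat(sprintf(
    "target_partition: A (lost) = %d, B (retained) = %d, C (off-target) = %d peaks\n",
    length(x$a_peaks), length(x$b_peaks), length(x$c_peaks)))
  if (length(x$a_genes) || length(x$b_genes) || length(x$c_genes)) {
    cat(sprintf("  genes: A = %d, B = %d, C = %d\n",
                length(x$a_genes), length(x$b_genes), length(x$c_genes)))
  }
  invisible(x)
}

# Regulatory domains under the basal-plus-extension rule. Returns a
# data.frame with one row per gene: chrom, domain start/end (BED half-open).
# Basal domain is strand-aware; the extension on each side runs to the
# nearest neighbouring basal domain or to max_ext from the TSS, whichever
# comes first, and never shrinks the basal domain.
regulatory_domains <- function(genes, basal_up = 6500, basal_down = 2500,
                               max_ext = 100000) {
  stopifnot(all(c("gene_id", "chrom", "tss", "strand") %in% names(genes)))
  plus <- genes$strand == "+"
  basal_start <- ifelse(plus, genes$tss - basal_up, genes$tss - basal_down)
  basal_end <- ifelse(plus, genes$tss + basal_down, genes$tss + basal_up)
  basal_start <- pmax(basal_start, 0)
  dom_start <- numeric(nrow(genes))
  dom_end <- numeric(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    same <- genes$chrom == genes$chrom[i]
    same[i] <- FALSE
    left_ends <- basal_end[same & basal_start < basal_start[i]]
    right_starts <- basal_start[same & basal_end > basal_end[i]]
    left_stop <- if (length(left_ends)) max(left_ends) else -Inf
    right_stop <- if (length(right_starts)) min(right_starts) else Inf
    ext_l <- max(genes$tss[i] - max_ext, min(left_stop, basal_start[i]))
    ext_r <- min(genes$tss[i] + max_ext, max(right_stop, basal_end[i]))
    dom_start[i] <- max(0, min(basal_start[i], ext_l))
    dom_end[i] <- max(basal_end[i], ext_r)
  }
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
             start = dom_start, end = dom_end, stringsAsFactors = FALSE)
}

#' Assign peaks to genes by basal-plus-extension regulatory domains
#'
#' Each gene gets a strand-aware basal domain (`basal_up` bp upstream and
#' `basal_down` bp downstream of its TSS) extended on both sides up to the
#' nearest neighbouring basal domain or `max_ext` bp from the TSS,
#' whichever is closer. A peak is assigned to every gene whose regulatory
#' domain contains the peak midpoint.
#'
#' @param peaks a `peak_set`.
#' @param genes data.frame with columns `gene_id`, `chrom`, `tss`
#'   (0-based bp), `strand` (`"+"`/`"-"`).
#' @param basal_up,basal_down,max_ext domain parameters in bp; defaults
#'   6500/2500/100000.
#' @return Named list: for each peak name, the character vector of assigned
#'   gene ids (possibly empty).
#' @export
assign_genes <- function(peaks, genes, basal_up = 6500, basal_down = 2500,
                         max_ext = 100000) {
  stopifnot(inherits(peaks, "peak_set"))
  peak_chroms <- unique(as.character(GenomicRanges::seqnames(peaks$gr)))
  unknown <- !(genes$chrom %in% peak_chroms)
  if (any(unknown) && length(peaks) > 0) {
    warning(sprintf("%d gene(s) on chromosomes absent from the peak set; skipped",
                    sum(unknown)))
    genes <- genes[!unknown, , drop = FALSE]
  }
  out <- stats::setNames(vector("list", length(peaks$gr)), names(peaks$gr))
  for (i in seq_along(out)) out[[i]] <- character(0)
  if (nrow(genes) == 0 || length(peaks) == 0) return(out)
  dom <- regulatory_domains(genes, basal_up, basal_down, max_ext)
  # midpoints in BED coordinates
  mid <- floor((GenomicRanges::start(peaks$gr) - 1L +
                GenomicRanges::end(peaks$gr)) / 2)
  pk_chrom <- as.character(GenomicRanges::seqnames(peaks$gr))
  for (i in seq_along(out)) {
    hit <- dom$chrom == pk_chrom[i] & dom$start <= mid[i] & mid[i] < dom$end
    out[[i]] <- unique(dom$gene_id[hit])
  }
  out
}

#' Fill gene-level A/B/C sets of a target partition
#'
#' Gene sets are the unions of gene assignments over the peaks of each
#' subset; the B gene set unions both the WT-side and variant-side retained
#' peaks.
#'
#' @param partition a `target_partition` from [classify_targets()].
#' @param assignment named list from [assign_genes()] covering the peaks of
#'   all subsets (peaks absent from the assignment contribute no genes).
#' @return The updated `target_partition`.
#' @export
partition_gene_sets <- function(partition, assignment) {
  stopifnot(inherits(partition, "target_partition"))
  genes_of <- function(ps) {
    nm <- names(ps$gr)
    found <- nm[nm %in% names(assignment)]
    sort(unique(unlist(assignment[found], use.names = FALSE)))
  }
  partition$a_genes <- genes_of(partition$a_peaks)
  partition$b_genes <- sort(unique(c(genes_of(partition$b_peaks),
                                     genes_of(partition$b_peaks_variant))))
  partition$c_genes <- genes_of(partition$c_peaks)
  partition
}
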