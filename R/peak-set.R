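#' Construct a peak set
#'
#' A `peak_set` is an allele-labelled, sorted, merged set of genomic
#' intervals. Coordinates follow the BED convention (0-based, half-open)
#' at the interface; internally intervals are held as a
#' [GenomicRanges::GRanges]. Overlapping and bookended (adjacent) intervals
#' are merged on construction, so all downstream set arithmetic operates on
#' disjoint intervals.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open (BED).
#' @param allele single label for the allele this set belongs to
#'   (e.g. `"WT"`, `"R189G"`).
#' @param name optional peak names; defaults to `chrom:start-end` after
#'   merging.
#' @return A `peak_set` object.
#' @export
peak_set <- function(chrom, start, end, allele = "WT", name = NULL) {
  if (length(chrom) == 1 && length(start) > 1) {
    chrom <- rep(chrom, length(start))
  }
  stopifnot(length(chrom) == length(start), length(start) == length(end))
  if (length(start) > 0) {
    if (any(start < 0) || any(end <= start)) {
      stop("intervals must satisfy 0 <= start < end (BED half-open)")
    }
  }
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(chrom),
    ranges = IRanges::IRanges(start = as.integer(start) + 1L,
                              end = as.integer(end))
  )
  merged <- GenomicRanges::reduce(GenomicRanges::sort(gr))
  if (!is.null(name) && length(name) == length(merged)) {
    names(merged) <- name
  } else if (length(merged) > 0) {
    names(merged) <- paste0(as.character(GenomicRanges::seqnames(merged)),
                            ":", GenomicRanges::start(merged) - 1L, "-",
                            GenomicRanges::end(merged))
  }
  structure(list(allele = as.character(allele), gr = merged),
            class = "peak_set")
}

peak_set_from_granges <- function(gr, allele) {
  ps <- structure(list(allele = as.character(allele), gr = gr),
                  class = "peak_set")
  if (is.null(names(ps$gr)) && length(gr) > 0) {
    names(ps$gr) <- paste0(GenomicRanges::seqnames(gr), ":",
                           GenomicRanges::start(gr) - 1L, "-",
                           GenomicRanges::end(gr))
  }
  ps
}

#' @export
length.peak_set <- function(x) length(x$gr)

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("peak_set: allele=%s, %d merged intervals, %d bp total\n",
              x$allele, length(x$gr), total_bp(x)))
  invisible(x)
}

#' @export
as.data.frame.peak_set <- function(x, ...) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(x$gr)),
    start = GenomicRanges::start(x$gr) - 1L,
    end = GenomicRanges::end(x$gr),
    name = names(x$gr),
    stringsAsFactors = FALSE
  )
}

#' Total genomic extent of a peak set in base pairs
#' @param x a `peak_set`.
#' @return integer, summed interval widths.
#' @export
total_bp <- function(x) {
  stopifnot(inherits(x, "peak_set"))
  sum(GenomicRanges::width(x$gr))
}

#' Read a BED file into a peak set
#'
#' Only the first three (or four, for names) columns are used.
#'
#' @param path BED file path.
#' @param allele allele label to attach.
#' @return A `peak_set`.
#' @export
read_peaks_bed <- function(path, allele = "WT") {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  nm <- if (ncol(df) >= 4) as.character(df[[4]]) else NULL
  peak_set(df[[1]], df[[2]], df[[3]], allele = allele, name = nm)
}

#' Write a peak set to BED (0-based half-open)
#' @param x a `peak_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_peaks_bed <- function(x, path) {
  df <- as.data.frame(x)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
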