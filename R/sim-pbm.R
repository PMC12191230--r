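#' Simulate a protein-binding-microarray probe table
#'
#' Probe intensities are driven by a planted 8-mer affinity landscape: each
#' probe's clean intensity is `min_intensity + a * (max_intensity -
#' min_intensity)` where `a` is the maximum affinity of any 8-mer contained
#' in the probe on either strand (the max rule keeps planted landscapes
#' interpretable), plus Gaussian noise. Probes containing no mapped 8-mer
#' sit at the baseline.
#'
#' @param affinity_map named numeric vector: 8-mer (ACGT) -> relative
#'   affinity in \[0, 1\]. Must be non-empty.
#' @param n_probes number of probes (default 60000, mirroring an
#'   8x60K universal-array layout).
#' @param probe_length probe length in nt (>= 8; default 36).
#' @param noise_sd Gaussian noise SD in intensity units.
#' @param min_intensity,max_intensity intensity range the affinity scale
#'   maps onto.
#' @param gc background GC fraction of the random probe sequences.
#' @param seed integer seed.
#' @return data.frame (`probe_id`, `sequence`, `intensity`) with attributes
#'   `affinity_map` (the truth landscape) and `probe_affinity`.
#' @export
simulate_pbm <- function(affinity_map, n_probes = 60000, probe_length = 36,
                         noise_sd = 0, min_intensity = 1000,
                         max_intensity = 60000, gc = 0.5, seed) {
  if (length(affinity_map) == 0) stop("affinity_map must be non-empty")
  keys <- names(affinity_map)
  if (is.null(keys) || any(nchar(keys) != 8) ||
      any(grepl("[^ACGT]", keys))) {
    stop("affinity_map keys must be 8-mers over {A,C,G,T}")
  }
  stopifnot(probe_length >= 8, noise_sd >= 0,
            all(affinity_map >= 0 & affinity_map <= 1))
  with_seed(seed, {
    seqs <- random_dna(n_probes, probe_length, gc)
    affinity <- numeric(n_probes)
    for (k in keys) {
      hit <- grepl(k, seqs, fixed = TRUE) |
        grepl(revcomp(k), seqs, fixed = TRUE)
      affinity[hit] <- pmax(affinity[hit], affinity_map[[k]])
    }
    intensity <- min_intensity + affinity * (max_intensity - min_intensity)
    if (noise_sd > 0) intensity <- intensity + stats::rnorm(n_probes, 0, noise_sd)
    out <- data.frame(
      probe_id = sprintf("probe_%06d", seq_len(n_probes)),
      sequence = seqs,
      intensity = intensity,
      stringsAsFactors = FALSE
    )
    attr(out, "affinity_map") <- affinity_map
    attr(out, "probe_affinity") <- affinity
    out
  })
}
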