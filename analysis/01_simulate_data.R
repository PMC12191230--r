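#!/usr/bin/env Rscript
# Generate the synthetic study inputs for the whole workflow: a peak
# universe with planted shared/lost/gained structure for a WT factor and
# two variants (one losing targets, one switching specificity), PBM probe
# tables driven by planted 8-mer affinity landscapes, fast- (20 ms) and
# slow- (500 ms) modality single-molecule trajectories per cell, and Y2H
# fluorescence readings. Everything is seed-deterministic and written as
# plain text under results/data/.

suppressMessages(library(tfscope))
seed <- 20260925
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

## ---- genomics arm: peak universes ------------------------------------
# varL loses ~40% of WT targets and gains a few off-targets; peaks carry
# the NKE core with a high-affinity 5'-C flank at 60% of WT sites
universe <- simulate_peak_universe(
  n_shared = 120, n_lost = 80, n_gained = 25,
  genome_length = 5e6, n_chrom = 3, peak_width = 500,
  planted_motifs = list(list(kmer = "CCACTTA", fraction = 0.6, copies = 2)),
  gained_motifs = list(list(kmer = "GCTAATGG", fraction = 0.8, copies = 2)),
  gc_background = 0.45, seed = seed)

write_peaks_bed(universe$wt, file.path(out, "wt_peaks.bed"))
write_peaks_bed(universe$variant, file.path(out, "varL_peaks.bed"))
write_fasta(universe$sequences, file.path(out, "peak_sequences.fa"))
write.csv(universe$truth, file.path(out, "peak_truth.csv"), row.names = FALSE)

# one gene per 20 kb on each chromosome as a toy TSS table
genes <- do.call(rbind, lapply(1:3, function(cc) {
  tss <- seq(10000, 5e6 - 10000, by = 20000)
  data.frame(gene_id = sprintf("gene_chr%d_%04d", cc, seq_along(tss)),
             chrom = paste0("chr", cc), tss = tss,
             strand = rep(c("+", "-"), length.out = length(tss)))
}))
write.table(genes, file.path(out, "genes.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)

## ---- PBM arm ----------------------------------------------------------
# WT binds the flanked NKE family; varS has switched to HOX-like sites
family <- function(core) {
  k <- nchar(core); bases <- c("A", "C", "G", "T")
  out <- character(0)
  for (off in 0:(8 - k)) {
    fills <- expand.grid(rep(list(bases), 8 - k),
                         stringsAsFactors = FALSE)
    for (r in seq_len(max(nrow(fills), 1))) {
      fill <- if (ncol(fills)) unlist(fills[r, ]) else character(0)
      pre <- paste(head(fill, off), collapse = "")
      post <- paste(tail(fill, length(fill) - off), collapse = "")
      out <- c(out, paste0(pre, core, post))
    }
  }
  setNames(rep(1.0, length(unique(out))), unique(out))
}
pbm_wt <- simulate_pbm(family("CCACTT"), n_probes = 60000,
                       probe_length = 20, noise_sd = 2000, seed = seed + 1)
pbm_varS <- simulate_pbm(family("TAAT"), n_probes = 60000,
                         probe_length = 20, noise_sd = 2000, seed = seed + 2)
write.csv(pbm_wt, file.path(out, "pbm_wt.csv"), row.names = FALSE)
write.csv(pbm_varS, file.path(out, "pbm_varS.csv"), row.names = FALSE)

## ---- SMT arm ----------------------------------------------------------
# fast modality (20 ms): WT is one-third bound; varL has lost most binding
smt_pars <- list(
  WT = list(F = c(0.35, 0.30, 0.35), D = c(0.01, 0.15, 1.0)),
  varL = list(F = c(0.10, 0.35, 0.55), D = c(0.01, 0.18, 1.1))
)
for (allele in names(smt_pars)) {
  p <- smt_pars[[allele]]
  for (cell in 1:4) {
    tr <- simulate_trajectories(
      1200, frame_interval = 0.02, n_frames = 40, fractions = p$F,
      D = p$D, loc_error_sd = 0.035, bleach_rate = 4, fov = c(256, 256),
      seed = seed + 10 * cell + match(allele, names(smt_pars)))
    write_tracks_csv(tr, file.path(out, sprintf("fast_%s_cell%d.csv",
                                                allele, cell)))
  }
}
# slow modality (500 ms): residence times; varL dwells ~30% shorter
dwell_pars <- list(WT = c(5, 0.9), varL = c(3.5, 0.65))
for (allele in names(dwell_pars)) {
  tp <- dwell_pars[[allele]]
  dw <- simulate_dwell_data(tau_long = tp[1], tau_short = tp[2],
                            frac_long = 0.5, n_tracks = 2000,
                            frame_interval = 0.5, censor_at = 250,
                            seed = seed + 100 + match(allele,
                                                      names(dwell_pars)))
  write.csv(data.frame(allele = allele, dwell_s = as.numeric(dw)),
            file.path(out, sprintf("dwell_%s.csv", allele)),
            row.names = FALSE)
}

## ---- Y2H --------------------------------------------------------------
y2h <- simulate_y2h(
  data.frame(bait = c("WT", "varL", "varS"),
             prey = "HAND1", strength = c(1.0, 0.45, 0.12)),
  n_replicates = 4, seed = seed + 200)
write.csv(y2h, file.path(out, "y2h.csv"), row.names = FALSE)

cat("wrote synthetic inputs to", out, "\n")
cat(sprintf("  peaks: WT %d, varL %d (planted %d shared / %d lost / %d gained)\n",
            length(universe$wt), length(universe$variant), 120, 80, 25))
cat(sprintf("  PBM: 2 x 60000 probes; SMT: 8 fast cells, 2 dwell sets; Y2H: %d rows\n",
            nrow(y2h)))
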