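#!/usr/bin/env Rscript
# Motif logic and in-vitro binding landscapes: flanking-base preference
# around the NKE core in peak sequences, permutation enrichment of the
# planted motif, 8-mer E-scores for the WT and specificity-switched
# variant PBM tables, and the per-class comparison of their significant
# 8-mers.

suppressMessages(library(tfscope))
data_dir <- "results/data"
out <- "results/motifs"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

seqs <- read_fasta(file.path(data_dir, "peak_sequences.fa"))
truth <- read.csv(file.path(data_dir, "peak_truth.csv"),
                  stringsAsFactors = FALSE)
wt_seqs <- seqs[truth$name[truth$label %in% c("shared", "lost")]]

## flanking bases around the NKE core in WT-bound peaks
flank <- flank_preference(wt_seqs, core = "CACTT")
write.csv(as.data.frame(flank), file.path(out, "flank_counts.csv"))
five <- rownames(flank)[which.max(flank[, "five_prime"])]
three <- rownames(flank)[which.max(flank[, "three_prime"])]
cat(sprintf("modal flanks around CACTT in WT peaks: 5'-%s, 3'-%s\n",
            five, three))

## permutation enrichment of the planted flanked core
z <- enrichment_z(wt_seqs[1:150], "CCACTTA", n_perm = 300, seed = 11)
cat(sprintf("dinucleotide-shuffle Z for CCACTTA in WT peaks: %.1f\n",
            as.numeric(z)))

## E-score landscapes
pbm_wt <- read.csv(file.path(data_dir, "pbm_wt.csv"),
                   stringsAsFactors = FALSE)
pbm_varS <- read.csv(file.path(data_dir, "pbm_varS.csv"),
                     stringsAsFactors = FALSE)
tab_wt <- escore_table(pbm_wt)
tab_varS <- escore_table(pbm_varS)
write.csv(tab_wt, file.path(out, "escore_wt.csv"), row.names = FALSE)
write.csv(tab_varS, file.path(out, "escore_varS.csv"), row.names = FALSE)

cmp <- compare_landscapes(tab_wt, tab_varS, cutoff = 0.35)
cat(sprintf("significant 8-mers (E > 0.35): WT %d, varS %d\n",
            cmp$n_significant[["wt"]], cmp$n_significant[["var"]]))
print(cmp$class_counts)
fisher <- compare_class_proportions(
  setNames(cmp$class_counts[, "wt"], rownames(cmp$class_counts)),
  setNames(cmp$class_counts[, "var"], rownames(cmp$class_counts)))
write.csv(fisher, file.path(out, "class_fisher.csv"), row.names = FALSE)
cat(sprintf("HOX-like proportion: WT %.2f vs varS %.2f (Fisher p = %.3g)\n",
            cmp$class_counts["HOX_like", "wt"] / sum(cmp$class_counts[, "wt"]),
            cmp$class_counts["HOX_like", "var"] / sum(cmp$class_counts[, "var"]),
            fisher$p[fisher$class == "HOX_like"]))
jsonlite::write_json(
  list(n_significant = as.list(cmp$n_significant),
       shared = length(cmp$shared_significant),
       unique_wt = length(cmp$unique_wt),
       unique_var = length(cmp$unique_var)),
  file.path(out, "landscape_summary.json"), auto_unbox = TRUE, digits = NA)
cat("tables written to", out, "\n")
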