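# file checksum for the run manifest
file_md5 <- function(paths) unname(tools::md5sum(paths))

write_manifest <- function(out_dir, params, files) {
  manifest <- list(
    params = params,
    artifacts = lapply(files, function(f) {
      list(path = basename(f), md5 = file_md5(f))
    })
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  path
}

#' Run the genomics arm end to end
#'
#' Jaccard footprinting, A/B/C target partitioning, gene assignment and
#' motif/flank analysis over a WT and a variant peak set. All outputs are
#' plain text (BED/CSV/JSON) under `out_dir`, listed with checksums in a
#' manifest so a rerun with identical inputs is byte-reproducible.
#'
#' @param wt,variant `peak_set` objects.
#' @param sequences named character vector of peak sequences (keyed by
#'   peak name).
#' @param genes optional gene table (`gene_id`, `chrom`, `tss`, `strand`).
#' @param out_dir output directory (created if needed).
#' @param core_motif motif core for flank and enrichment analysis.
#' @param min_overlap_bp,basal_up,basal_down,max_ext analysis parameters.
#' @param seed integer seed (recorded in the manifest).
#' @return List with the partition, Jaccard matrix, flank table and the
#'   manifest path.
#' @export
run_genomics_arm <- function(wt, variant, sequences, genes = NULL,
                             out_dir = "results/genomics",
                             core_motif = "CACTT", min_overlap_bp = 1,
                             basal_up = 6500, basal_down = 2500,
                             max_ext = 100000, seed = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jm <- jaccard_matrix(list(wt, variant))
  part <- classify_targets(wt, variant, min_overlap_bp = min_overlap_bp)
  if (!is.null(genes)) {
    asn_wt <- assign_genes(wt, genes, basal_up, basal_down, max_ext)
    asn_var <- assign_genes(variant, genes, basal_up, basal_down, max_ext)
    part <- partition_gene_sets(part, c(asn_wt, asn_var))
  }
  flank <- flank_preference(sequences, core = core_motif)

  files <- c(
    a = file.path(out_dir, "a_set.bed"),
    b = file.path(out_dir, "b_set.bed"),
    c = file.path(out_dir, "c_set.bed"),
    jaccard = file.path(out_dir, "jaccard_matrix.csv"),
    flank = file.path(out_dir, "flank_counts.csv"),
    summary = file.path(out_dir, "partition_summary.json")
  )
  write_peaks_bed(part$a_peaks, files["a"])
  write_peaks_bed(part$b_peaks, files["b"])
  write_peaks_bed(part$c_peaks, files["c"])
  utils::write.csv(as.data.frame(jm), files["jaccard"])
  utils::write.csv(as.data.frame(flank), files["flank"])
  jsonlite::write_json(
    list(n_a = length(part$a_peaks), n_b = length(part$b_peaks),
         n_c = length(part$c_peaks),
         a_genes = part$a_genes, b_genes = part$b_genes,
         c_genes = part$c_genes, seed = seed),
    files["summary"], auto_unbox = TRUE, digits = NA)
  manifest <- write_manifest(
    out_dir,
    params = list(min_overlap_bp = min_overlap_bp, basal_up = basal_up,
                  basal_down = basal_down, max_ext = max_ext,
                  core_motif = core_motif, seed = seed),
    files = as.list(files))
  list(partition = part, jaccard = jm, flank = flank, manifest = manifest)
}

#' Run the single-molecule-tracking arm end to end
#'
#' Fast-modality three-state fitting and per-cell feature extraction plus
#' slow-modality survival analysis, with IQR outlier removal across
#' cells. Inputs are per-cell `smt_tracks`; fit JSONs and per-cell CSV
#' summaries are written under `out_dir`.
#'
#' @param fast_cells named list of `smt_tracks` (20 ms modality), one per
#'   cell.
#' @param slow_cells named list of `smt_tracks` (500 ms modality).
#' @param out_dir output directory.
#' @param seed integer seed for the fits.
#' @param iqr_k IQR multiplier for per-cell outlier removal.
#' @return List with the pooled three-state fit, per-cell feature table,
#'   pooled survival fit, and the manifest path.
#' @export
run_smt_arm <- function(fast_cells, slow_cells,
                        out_dir = "results/smt", seed = 1, iqr_k = 1.5) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dts <- vapply(fast_cells, attr, numeric(1), "frame_interval")
  if (length(unique(dts)) > 1) stop("fast cells mix frame intervals")
  dts_s <- vapply(slow_cells, attr, numeric(1), "frame_interval")
  if (length(unique(dts_s)) > 1) stop("slow cells mix frame intervals")

  feats <- do.call(rbind, lapply(names(fast_cells), function(id) {
    cell_features(fast_cells[[id]], cell_id = id)
  }))
  qc_keep <- iqr_filter(feats$mean_D, k = iqr_k)
  feats$qc_pass <- qc_keep

  pooled_fast <- do.call(rbind, lapply(which(qc_keep), function(i) {
    tr <- as.data.frame(fast_cells[[i]])
    tr$track_id <- paste0(names(fast_cells)[i], "_", tr$track_id)
    tr
  }))
  fit3 <- if (!is.null(pooled_fast) && nrow(pooled_fast) > 0) {
    fit_three_state(smt_tracks(pooled_fast, unique(dts)), seed = seed)
  } else NULL

  dwells <- unlist(lapply(slow_cells, residence_times), use.names = FALSE)
  surv <- if (length(dwells) >= 10) {
    fit_exponentials(survival_curve(dwells), components = 2, seed = seed)
  } else NULL

  files <- c(cells = file.path(out_dir, "cell_features.csv"),
             fast = file.path(out_dir, "three_state_fit.json"),
             slow = file.path(out_dir, "survival_fit.json"))
  utils::write.csv(feats, files["cells"], row.names = FALSE)
  jsonlite::write_json(
    if (is.null(fit3)) list(empty = TRUE) else
      list(F = as.list(fit3$F), D = as.list(fit3$D), sigma = fit3$sigma,
           sse = fit3$sse, n_jumps = fit3$n_jumps, seed = seed),
    files["fast"], auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    if (is.null(surv)) list(empty = TRUE) else
      list(model = surv$model, tau_long = surv$tau_long,
           tau_short = surv$tau_short, frac_long = surv$frac_long,
           ratio_long_short = surv$ratio_long_short, sse = surv$sse,
           n_dwells = length(dwells), seed = seed),
    files["slow"], auto_unbox = TRUE, digits = NA)
  manifest <- write_manifest(out_dir,
                             params = list(seed = seed, iqr_k = iqr_k),
                             files = as.list(files))
  list(three_state = fit3, cell_features = feats, survival = surv,
       manifest = manifest)
}
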