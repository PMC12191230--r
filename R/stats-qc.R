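#' Interquartile-range outlier mask
#'
#' Keeps values inside `[Q1 - k*IQR, Q3 + k*IQR]`, quartiles by linear
#' interpolation (type 7). Fewer than 4 values: all kept with a warning.
#'
#' @param values numeric vector.
#' @param k IQR multiplier (default 1.5).
#' @return Logical keep-mask of the same length.
#' @export
iqr_filter <- function(values, k = 1.5) {
  if (length(values) < 4) {
    warning("fewer than 4 values: no outlier filtering applied")
    return(rep(TRUE, length(values)))
  }
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, na.rm = TRUE)
  iqr <- q[2] - q[1]
  values >= q[1] - k * iqr & values <= q[2] + k * iqr
}

#' Normalise and classify yeast-two-hybrid interactions
#'
#' Each record's growth ratio `f_t2 / f_t1` is normalised to the mean
#' ratio of the WT bait with the same prey, giving a per-pair score
#' (WT = 1 by construction). Scores are averaged over replicates and
#' classified: `normal` at or above `normal_min`, `perturbed` between
#' `absent_max` and `normal_min`, `absent` below `absent_max`.
#'
#' @param records data.frame (`bait`, `prey`, `replicate`, `f_t1`,
#'   `f_t2`).
#' @param wt_reference bait label of the WT reference (default `"WT"`).
#' @param normal_min,absent_max category thresholds (defaults 0.75, 0.25).
#' @return data.frame (`bait`, `prey`, `score`, `category`, `n_valid`);
#'   records with `f_t1 == 0` are flagged invalid and excluded from the
#'   score.
#' @export
y2h_normalize <- function(records, wt_reference = "WT",
                          normal_min = 0.75, absent_max = 0.25) {
  stopifnot(all(c("bait", "prey", "f_t1", "f_t2") %in% names(records)),
            all(records$f_t1 >= 0), all(records$f_t2 >= 0))
  valid <- records$f_t1 > 0
  if (any(!valid)) {
    warning(sum(!valid), " record(s) with f_t1 == 0 flagged invalid")
  }
  rec <- records[valid, , drop = FALSE]
  rec$ratio <- rec$f_t2 / rec$f_t1
  wt <- rec[rec$bait == wt_reference, , drop = FALSE]
  wt_ratio <- tapply(wt$ratio, wt$prey, mean)
  missing_ref <- setdiff(unique(rec$prey), names(wt_ratio))
  if (length(missing_ref)) {
    stop("no WT reference for prey: ", paste(missing_ref, collapse = ", "))
  }
  rec$score <- rec$ratio / as.numeric(wt_ratio[rec$prey])
  agg <- stats::aggregate(score ~ bait + prey, data = rec, FUN = mean)
  n <- stats::aggregate(score ~ bait + prey, data = rec, FUN = length)
  agg$n_valid <- n$score
  agg$category <- ifelse(agg$score >= normal_min, "normal",
                         ifelse(agg$score >= absent_max, "perturbed",
                                "absent"))
  agg[order(agg$bait, agg$prey), c("bait", "prey", "score", "category",
                                   "n_valid")]
}
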