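# displacements at a given frame lag within one track; jumps spanning
# gap-closed (missing) frames are excluded — frame difference must equal
# the lag exactly
lag_jumps <- function(tr, lag) {
  idx <- match(tr$frame + lag, tr$frame)
  ok <- !is.na(idx)
  if (!any(ok)) return(numeric(0))
  sqrt((tr$x[idx[ok]] - tr$x[ok])^2 + (tr$y[idx[ok]] - tr$y[ok])^2)
}

#' Time-averaged mean squared displacement of one trajectory
#'
#' `msd(n*dt)` is the mean squared displacement over all localization
#' pairs `n` frames apart, for lags up to `fraction_used` of the track
#' length.
#'
#' @param traj data.frame (`frame`, `x`, `y`) for one track.
#' @param frame_interval frame interval in s.
#' @param fraction_used fraction of the available lags used (default 0.9).
#' @return data.frame (`lag` in s, `msd` in um^2, `n_pairs`).
#' @export
msd_curve <- function(traj, frame_interval, fraction_used = 0.9) {
  L <- nrow(traj)
  stopifnot(L >= 2, fraction_used > 0, fraction_used <= 1)
  max_lag <- max(1L, floor(fraction_used * (L - 1L)))
  rows <- lapply(seq_len(max_lag), function(n) {
    r <- lag_jumps(traj, n)
    if (length(r) == 0) return(NULL)
    data.frame(lag = n * frame_interval, msd = mean(r^2),
               n_pairs = length(r))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  do.call(rbind, rows)
}

#' Fit a power law to an MSD curve
#'
#' Least-squares fit of `msd = 4 * D_app * t^alpha + offset`. `alpha = 1`
#' is free diffusion, `alpha < 1` subdiffusive/confined. The offset
#' absorbs the static localization-error plateau; `offset_init` is the
#' fit's initial offset value.
#'
#' @param curve data.frame from [msd_curve()] (>= 3 lags).
#' @param offset_init initial offset (default 0.5).
#' @return List (`D_app`, `alpha`, `offset`, `converged`,
#'   `fraction_used`); `NA` parameters with `converged = FALSE` when no
#'   start converges.
#' @export
fit_msd_powerlaw <- function(curve, offset_init = 0.5) {
  stopifnot(nrow(curve) >= 3)
  t <- curve$lag; y <- curve$msd
  fit_one <- function(start) {
    tryCatch(
      suppressWarnings(minpack.lm::nls.lm(
        par = start,
        lower = c(D = 1e-8, alpha = 1e-3, offset = 0),
        upper = c(D = Inf, alpha = 3, offset = Inf),
        fn = function(p) y - (4 * p[["D"]] * t^p[["alpha"]] + p[["offset"]])
      )),
      error = function(e) NULL
    )
  }
  d0 <- max((y[length(y)] - y[1]) / (4 * (t[length(t)] - t[1])), 1e-6)
  starts <- list(c(D = d0, alpha = 1, offset = offset_init),
                 c(D = d0, alpha = 1, offset = 0),
                 c(D = max(y[1] / (4 * t[1]), 1e-6), alpha = 1, offset = 0))
  fits <- lapply(starts, fit_one)
  fits <- fits[!vapply(fits, is.null, logical(1))]
  if (length(fits) == 0) {
    return(list(D_app = NA_real_, alpha = NA_real_, offset = NA_real_,
                converged = FALSE, fraction_used = NA_real_))
  }
  sse <- vapply(fits, function(f) sum(f$fvec^2), numeric(1))
  best <- fits[[which.min(sse)]]
  p <- best$par
  list(D_app = p[["D"]], alpha = p[["alpha"]], offset = p[["offset"]],
       converged = best$info %in% 1:4, fraction_used = 0.9)
}

#' Apparent diffusion coefficient of one trajectory
#'
#' `D = mean(r1^2) / (4 dt) - sigma_est^2 / dt` from one-frame jumps,
#' corrected for localization error and floored at `1e-6` um^2/s.
#'
#' @param traj data.frame (`frame`, `x`, `y`), >= 5 localizations.
#' @param frame_interval frame interval in s.
#' @param sigma_est localization error SD estimate in um.
#' @return D in um^2/s.
#' @export
per_track_diffusion <- function(traj, frame_interval, sigma_est = 0) {
  stopifnot(nrow(traj) >= 5)
  r <- lag_jumps(traj, 1L)
  if (length(r) == 0) return(1e-6)
  max(mean(r^2) / (4 * frame_interval) - sigma_est^2 / frame_interval, 1e-6)
}

#' Split per-track diffusion coefficients into mobile/immobile fractions
#'
#' @param track_Ds numeric vector of per-track D (um^2/s).
#' @param d_threshold split point in um^2/s; the default 0.1 matches the
#'   upper bound of the bound state in the three-state model.
#' @return Named vector (`mobile_fraction`, `immobile_fraction`), summing
#'   to 1. Tracks exactly at the threshold count as immobile.
#' @export
split_mobile_immobile <- function(track_Ds, d_threshold = 0.1) {
  stopifnot(length(track_Ds) >= 1)
  im <- mean(track_Ds <= d_threshold)
  c(mobile_fraction = 1 - im, immobile_fraction = im)
}

three_state_cdf <- function(r, tau, F3, D3, sigma) {
  s <- 4 * (D3 * tau + sigma^2)
  F3[1] * (1 - exp(-r^2 / s[1])) + F3[2] * (1 - exp(-r^2 / s[2])) +
    F3[3] * (1 - exp(-r^2 / s[3]))
}

#' Fit the three-state jump-distance model to pooled trajectories
#'
#' Pools jump distances over lags `1..n_lags` frames and fits the
#' three-state (bound / slow / fast) mixture to the empirical jump-length
#' cumulative distributions by constrained least squares:
#' `P(R <= r | lag tau) = sum_i F_i * (1 - exp(-r^2 / (4 (D_i tau +
#' sigma^2))))`, with `sum F_i = 1` enforced exactly through a simplex
#' parameterization and the localization error `sigma` fit from the data.
#' Multi-start (`n_init` random initializations inside the bounds) with
#' the best SSE returned.
#'
#' @param tracks an `smt_tracks` object (or list of per-track data.frames
#'   plus `frame_interval`).
#' @param frame_interval frame interval in s; taken from `tracks` when
#'   absent.
#' @param n_lags number of frame lags pooled (default 6).
#' @param n_init number of fitting initializations (default 10).
#' @param bounds list with `D_B`, `D_S`, `D_F`, `sigma` two-element ranges;
#'   defaults Bound 1e-5–0.1, Slow 1e-3–0.5, Fast 0.2–5 um^2/s, sigma
#'   0.005–0.1 um.
#' @param n_grid CDF evaluation points per lag (default 60).
#' @param seed integer seed for the random starts.
#' @return A `jump_model_fit` list: `F` (bound, slow, fast), `D`, `sigma`,
#'   `sse`, `n_jumps`, `converged`.
#' @export
fit_three_state <- function(tracks, frame_interval = NULL, n_lags = 6,
                            n_init = 10,
                            bounds = list(D_B = c(1e-5, 0.1),
                                          D_S = c(1e-3, 0.5),
                                          D_F = c(0.2, 5),
                                          sigma = c(0.005, 0.1)),
                            n_grid = 60, seed = 1) {
  dt <- frame_interval %||% attr(tracks, "frame_interval")
  stopifnot(!is.null(dt))
  trs <- if (inherits(tracks, "smt_tracks")) split_tracks(tracks) else tracks
  jumps <- lapply(seq_len(n_lags), function(n) {
    unlist(lapply(trs, lag_jumps, lag = n), use.names = FALSE)
  })
  n_jumps <- sum(lengths(jumps))
  if (n_jumps < 500) stop("need at least 500 pooled jumps, got ", n_jumps)

  # empirical CDF per lag on a common quantile-spanning grid
  grids <- lapply(jumps, function(r) {
    seq(0, stats::quantile(r, 0.995), length.out = n_grid)[-1]
  })
  emp <- lapply(seq_len(n_lags), function(i) {
    stats::ecdf(jumps[[i]])(grids[[i]])
  })

  lower <- c(0, 0, bounds$D_B[1], bounds$D_S[1], bounds$D_F[1],
             bounds$sigma[1])
  upper <- c(1, 1, bounds$D_B[2], bounds$D_S[2], bounds$D_F[2],
             bounds$sigma[2])
  resid_fn <- function(p) {
    F3 <- c(p[1], (1 - p[1]) * p[2], (1 - p[1]) * (1 - p[2]))
    D3 <- p[3:5]
    unlist(lapply(seq_len(n_lags), function(i) {
      emp[[i]] - three_state_cdf(grids[[i]], i * dt, F3, D3, p[6])
    }), use.names = FALSE)
  }
  with_seed(seed, {
    starts <- c(
      list(c(0.33, 0.5, 0.01, 0.15, 1.0, 0.035)),
      lapply(seq_len(max(n_init - 1, 0)), function(k) {
        stats::runif(6, lower, upper)
      })
    )
    fits <- lapply(starts, function(st) {
      tryCatch(
        suppressWarnings(
          minpack.lm::nls.lm(par = st, lower = lower, upper = upper,
                             fn = resid_fn,
                             control = minpack.lm::nls.lm.control(
                               maxiter = 200))),
        error = function(e) NULL
      )
    })
    fits <- fits[!vapply(fits, is.null, logical(1))]
    if (length(fits) == 0) {
      return(structure(list(F = rep(NA_real_, 3), D = rep(NA_real_, 3),
                            sigma = NA_real_, sse = NA_real_,
                            n_jumps = n_jumps, converged = FALSE),
                       class = "jump_model_fit"))
    }
    sse <- vapply(fits, function(f) sum(f$fvec^2), numeric(1))
    best <- fits[[which.min(sse)]]
    p <- best$par
    F3 <- c(p[1], (1 - p[1]) * p[2], (1 - p[1]) * (1 - p[2]))
    structure(list(
      F = stats::setNames(F3, c("bound", "slow", "fast")),
      D = stats::setNames(p[3:5], c("bound", "slow", "fast")),
      sigma = p[6], sse = min(sse), all_sse = sse, n_jumps = n_jumps,
      converged = best$info %in% 1:4
    ), class = "jump_model_fit")
  })
}

#' @export
print.jump_model_fit <- function(x, ...) {
  cat("three-state jump-distance model fit\n")
  cat(sprintf("  fractions: bound %.3f, slow %.3f, fast %.3f\n",
              x$F[1], x$F[2], x$F[3]))
  cat(sprintf("  D (um^2/s): bound %.4g, slow %.4g, fast %.4g\n",
              x$D[1], x$D[2], x$D[3]))
  cat(sprintf("  sigma = %.4f um, sse = %.4g, %d jumps\n",
              x$sigma, x$sse, x$n_jumps))
  invisible(x)
}

#' Jump angles between consecutive displacements
#'
#' For each pair of consecutive displacements (consecutive frames only —
#' jumps spanning gap-closed frames are excluded) with both jump lengths
#' above `min_jump`, the angle between them folded to \[0, 180\] degrees:
#' 0 = forward continuation, 180 = reversal.
#'
#' @param traj data.frame (`frame`, `x`, `y`), >= 3 localizations.
#' @param min_jump minimum jump length in um (default 0.125).
#' @return Numeric vector of angles in degrees.
#' @export
jump_angles <- function(traj, min_jump = 0.125) {
  stopifnot(nrow(traj) >= 3)
  o <- order(traj$frame)
  f <- traj$frame[o]; x <- traj$x[o]; y <- traj$y[o]
  consec <- which(diff(f) == 1)
  # need two consecutive one-frame jumps: i -> i+1 -> i+2
  first <- consec[(consec + 1) %in% consec]
  if (length(first) == 0) return(numeric(0))
  v1x <- x[first + 1] - x[first]; v1y <- y[first + 1] - y[first]
  v2x <- x[first + 2] - x[first + 1]; v2y <- y[first + 2] - y[first + 1]
  l1 <- sqrt(v1x^2 + v1y^2); l2 <- sqrt(v2x^2 + v2y^2)
  ok <- l1 > min_jump & l2 > min_jump
  if (!any(ok)) return(numeric(0))
  cosang <- (v1x[ok] * v2x[ok] + v1y[ok] * v2y[ok]) / (l1[ok] * l2[ok])
  acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
}

#' Fold anisotropy ratio of a jump-angle distribution
#'
#' Ratio of reversal-like angles (within `window` degrees of 180) to
#' forward-like angles (within `window` of 0). 1 = isotropic; > 1 =
#' excess reversals, the signature of confined or recurrent search.
#'
#' @param angles numeric vector of angles in degrees (\[0, 180\]).
#' @param window window width in degrees (default 30).
#' @return The ratio; `Inf` with attribute `flag = "empty_forward"` when
#'   no angle falls in the forward window.
#' @export
anisotropy <- function(angles, window = 30) {
  backw <- sum(angles >= 180 - window)
  forw <- sum(angles <= window)
  if (forw == 0) {
    return(structure(Inf, flag = "empty_forward"))
  }
  backw / forw
}

#' Confinement radius of one trajectory
#'
#' The maximum distance of any localization from the trajectory centroid
#' (default), or the radius of gyration.
#'
#' @param traj data.frame (`frame`, `x`, `y`), >= 5 localizations.
#' @param method `"max"` (default) or `"gyration"`.
#' @return Radius in um.
#' @export
confinement_radius <- function(traj, method = c("max", "gyration")) {
  method <- match.arg(method)
  stopifnot(nrow(traj) >= 5)
  cx <- mean(traj$x); cy <- mean(traj$y)
  d2 <- (traj$x - cx)^2 + (traj$y - cy)^2
  if (method == "max") sqrt(max(d2)) else sqrt(mean(d2))
}

#' Per-cell summary of single-molecule dynamics
#'
#' Aggregates per-track metrics into one row per cell: mean per-track
#' diffusion coefficient, mean one-frame jump distance, mean confinement
#' radius, fold-anisotropy ratio of the pooled angles, and the
#' mobile/immobile split.
#'
#' @param tracks an `smt_tracks` object (one cell's trajectories).
#' @param cell_id label for the cell.
#' @param sigma_est localization error estimate (um) for per-track D.
#' @param d_threshold mobile/immobile split (um^2/s).
#' @param min_jump anisotropy jump threshold (um).
#' @param min_length minimum track length used (default 5).
#' @return One-row data.frame of features.
#' @export
cell_features <- function(tracks, cell_id = "cell", sigma_est = 0.035,
                          d_threshold = 0.1, min_jump = 0.125,
                          min_length = 5) {
  dt <- attr(tracks, "frame_interval")
  trs <- Filter(function(tr) nrow(tr) >= min_length, split_tracks(tracks))
  stopifnot(length(trs) >= 1)
  Ds <- vapply(trs, per_track_diffusion, numeric(1),
               frame_interval = dt, sigma_est = sigma_est)
  jumps <- unlist(lapply(trs, lag_jumps, lag = 1L), use.names = FALSE)
  radii <- vapply(trs, confinement_radius, numeric(1))
  angles <- unlist(lapply(trs, jump_angles, min_jump = min_jump),
                   use.names = FALSE)
  aniso <- if (length(angles)) as.numeric(anisotropy(angles)) else NA_real_
  mob <- split_mobile_immobile(Ds, d_threshold)
  data.frame(cell_id = cell_id,
             mean_D = mean(Ds),
             mean_jump = mean(jumps),
             mean_confinement = mean(radii),
             anisotropy = aniso,
             mobile_fraction = unname(mob["mobile_fraction"]),
             n_tracks = length(trs),
             stringsAsFactors = FALSE)
}

#' PCA over per-cell dynamic features
#'
#' Features are standardized; constant features are dropped with a
#' warning. Sign convention: each component is oriented so its
#' largest-magnitude loading is positive, making the output deterministic.
#'
#' @param summaries data.frame of [cell_features()] rows (>= 3 cells).
#' @param features which columns to use.
#' @return List (`scores` cells x PCs, `explained_variance` proportions,
#'   `loadings`).
#' @export
features_pca <- function(summaries,
                         features = c("mean_D", "mean_jump",
                                      "mean_confinement", "anisotropy",
                                      "mobile_fraction")) {
  stopifnot(nrow(summaries) >= 3)
  X <- as.matrix(summaries[, features, drop = FALSE])
  keep <- apply(X, 2, function(v) stats::sd(v) > 0 && all(is.finite(v)))
  if (!all(keep)) {
    warning("dropping constant/non-finite feature(s): ",
            paste(features[!keep], collapse = ", "))
  }
  X <- X[, keep, drop = FALSE]
  if (ncol(X) == 0) {
    n <- nrow(summaries)
    return(list(scores = matrix(0, n, 2,
                                dimnames = list(summaries$cell_id,
                                                c("PC1", "PC2"))),
                explained_variance = c(0, 0), loadings = NULL))
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  for (j in seq_len(ncol(pc$rotation))) {
    i_max <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i_max, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  rownames(pc$x) <- summaries$cell_id
  list(scores = pc$x,
       explained_variance = pc$sdev^2 / sum(pc$sdev^2),
       loadings = pc$rotation)
}
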