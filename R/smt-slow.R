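#' Residence times of the immobile population from slow-modality tracks
#'
#' Each track's residence time is `(last frame - first frame + 1) * dt`.
#' Tracks whose apparent per-track diffusion coefficient exceeds `d_max`
#' (default 0.05 um^2/s, the slow modality's maximum expected D) are
#' excluded as not stably bound; tracks too short for a D estimate are
#' kept.
#'
#' @param tracks an `smt_tracks` object (slow modality).
#' @param d_max exclusion threshold on per-track D (um^2/s).
#' @param sigma_est localization error estimate for the D filter (um).
#' @return Numeric vector of residence times in s.
#' @export
residence_times <- function(tracks, d_max = 0.05, sigma_est = 0) {
  dt <- attr(tracks, "frame_interval")
  stopifnot(!is.null(dt))
  trs <- split_tracks(tracks)
  if (length(trs) == 0) return(numeric(0))
  keep <- vapply(trs, function(tr) {
    if (nrow(tr) < 5) return(TRUE)
    per_track_diffusion(tr, dt, sigma_est) <= d_max
  }, logical(1))
  vapply(trs[keep], function(tr) {
    (max(tr$frame) - min(tr$frame) + 1) * dt
  }, numeric(1), USE.NAMES = FALSE)
}

#' Dwell-time survival function
#'
#' `S(t)` = fraction of residence times at least `t`, evaluated at the
#' observed (quantized) times. Monotone non-increasing with
#' `S(min time) = 1`.
#'
#' @param durations numeric vector of residence times (>= 10).
#' @return data.frame (`t`, `S`).
#' @export
survival_curve <- function(durations) {
  stopifnot(length(durations) >= 10)
  t <- sort(unique(durations))
  S <- vapply(t, function(tt) mean(durations >= tt), numeric(1))
  data.frame(t = t, S = S)
}

#' Fit exponential decay components to a survival curve
#'
#' Least-squares fit of the survival function with the time axis shifted
#' so the first observed time point is zero (frame quantization makes the
#' shifted exponential mixture exact: a dwell quantized upward to `k`
#' frames survives to `k*dt` iff the underlying dwell exceeds
#' `(k-1)*dt`). One component: `S = exp(-k (t - t0))`. Two components:
#' `S = f * exp(-k_long (t - t0)) + (1 - f) * exp(-k_short (t - t0))` with
#' `k_long < k_short`. Multi-start least squares; if the two recovered
#' time constants are closer than one frame interval the fit is flagged
#' degenerate and collapses to the one-component answer.
#'
#' @param curve data.frame from [survival_curve()] (>= 5 time points).
#' @param components 1 or 2.
#' @param n_init number of random starts (default 10).
#' @param frame_interval frame interval in s, used for the degeneracy
#'   guard; defaults to the smallest spacing of the curve's time grid.
#' @param seed integer seed.
#' @return A `survival_fit` list: `model`, `k_long`, `k_short`,
#'   `frac_long`, `tau_long`, `tau_short`, `ratio_long_short`, `sse`,
#'   `degenerate`, `converged`.
#' @export
fit_exponentials <- function(curve, components = 2, n_init = 10,
                             frame_interval = NULL, seed = 1) {
  stopifnot(components %in% c(1, 2), nrow(curve) >= 5)
  t0 <- min(curve$t)
  t <- curve$t - t0
  S <- curve$S
  dt <- frame_interval %||% min(diff(sort(unique(curve$t))))

  fit1 <- function() {
    # 1-exp is linear in log space for a first pass, then refined
    k0 <- if (any(S > 0 & t > 0)) {
      -stats::coef(stats::lm(log(pmax(S, 1e-12)) ~ t - 1))[[1]]
    } else 1
    f <- minpack.lm::nls.lm(par = c(k = max(k0, 1e-6)),
                            lower = c(k = 1e-8),
                            fn = function(p) S - exp(-p[["k"]] * t))
    list(model = "1-exp", k_long = f$par[["k"]], k_short = f$par[["k"]],
         frac_long = 1, sse = sum(f$fvec^2),
         converged = f$info %in% 1:4)
  }

  if (components == 1) {
    out <- fit1()
  } else {
    resid2 <- function(p) {
      S - (p[3] * exp(-p[1] * t) + (1 - p[3]) * exp(-p[2] * t))
    }
    with_seed(seed, {
      base <- fit1()
      starts <- c(
        list(c(base$k_long / 3, base$k_long * 3, 0.5)),
        lapply(seq_len(max(n_init - 1, 0)), function(i) {
          c(base$k_long * stats::runif(1, 0.05, 1),
            base$k_long * stats::runif(1, 1, 20),
            stats::runif(1))
        })
      )
      fits <- lapply(starts, function(st) {
        tryCatch(
          suppressWarnings(
            minpack.lm::nls.lm(par = st, lower = c(1e-8, 1e-8, 0),
                               upper = c(Inf, Inf, 1), fn = resid2,
                               control = minpack.lm::nls.lm.control(
                                 maxiter = 200))),
          error = function(e) NULL
        )
      })
      fits <- fits[!vapply(fits, is.null, logical(1))]
      if (length(fits) == 0) {
        out <- list(model = "2-exp", k_long = NA_real_, k_short = NA_real_,
                    frac_long = NA_real_, sse = NA_real_, converged = FALSE)
      } else {
        sse <- vapply(fits, function(f) sum(f$fvec^2), numeric(1))
        best <- fits[[which.min(sse)]]
        p <- best$par
        # order so the long-lived component has the smaller rate
        if (p[1] > p[2]) p <- c(p[2], p[1], 1 - p[3])
        out <- list(model = "2-exp", k_long = p[1], k_short = p[2],
                    frac_long = p[3], sse = min(sse),
                    converged = best$info %in% 1:4)
      }
    })
  }
  out$tau_long <- 1 / out$k_long
  out$tau_short <- 1 / out$k_short
  out$degenerate <- FALSE
  if (components == 2 && is.finite(out$tau_long) &&
      abs(out$tau_long - out$tau_short) < dt) {
    # identifiability guard: components closer than one frame interval
    one <- fit1()
    out$model <- "1-exp"
    out$k_long <- out$k_short <- one$k_long
    out$tau_long <- out$tau_short <- 1 / one$k_long
    out$frac_long <- 1
    out$sse <- one$sse
    out$degenerate <- TRUE
    out$converged <- one$converged
  }
  out$ratio_long_short <- if (out$frac_long < 1) {
    out$frac_long / (1 - out$frac_long)
  } else Inf
  structure(out, class = "survival_fit")
}

#' @export
print.survival_fit <- function(x, ...) {
  cat(sprintf("survival_fit (%s%s)\n", x$model,
              if (x$degenerate) ", degenerate" else ""))
  cat(sprintf("  tau_long = %.3f s, tau_short = %.3f s, frac_long = %.3f\n",
              x$tau_long, x$tau_short, x$frac_long))
  cat(sprintf("  long/short fraction ratio = %.3f, sse = %.4g\n",
              x$ratio_long_short, x$sse))
  invisible(x)
}
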