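#' Simulate single-molecule 2D trajectories from a 3-state diffusion model
#'
#' Each molecule is assigned a mobility state (bound, slow, fast) with the
#' configured probabilities and performs 2D Brownian motion at that state's
#' diffusion coefficient: per-frame displacements per axis are
#' `Normal(0, 2*D*dt)`. Observed positions add Gaussian localization error
#' per axis. Track length is geometric from the bleaching rate (capped at
#' `n_frames`), and a track also terminates if the true position leaves the
#' field of view. By default states are static for the lifetime of a track;
#' a continuous-time switching matrix can be supplied as a stress-test
#' mode, in which case within-frame diffusion variance integrates D over
#' the state path.
#'
#' @param n_molecules number of molecules.
#' @param frame_interval frame interval in s (0.020 fast, 0.500 slow).
#' @param n_frames acquisition length in frames.
#' @param fractions length-3 state probabilities (bound, slow, fast);
#'   must sum to 1.
#' @param D length-3 diffusion coefficients in um^2/s, non-decreasing.
#' @param switch_rates optional 3x3 per-second rate matrix (off-diagonal
#'   switching rates; diagonal ignored). NULL (default) = static states.
#' @param loc_error_sd localization error SD per axis, um.
#' @param bleach_rate photobleaching rate per s (0 = no bleaching).
#' @param pixel_size um per pixel (default 0.1).
#' @param fov field of view in pixels, length-2 (width, height).
#' @param seed integer seed.
#' @return An `smt_tracks` object: data.frame (`track_id`, `frame`, `x`,
#'   `y` in um) with attributes `frame_interval`, `pixel_size`, and `truth`
#'   (data.frame `track_id`, `state` of the initial state, plus the full
#'   per-frame state path in `truth_states`).
#' @export
simulate_trajectories <- function(n_molecules, frame_interval = 0.02,
                                  n_frames = 100,
                                  fractions = c(0.3, 0.3, 0.4),
                                  D = c(0.01, 0.15, 1.0),
                                  switch_rates = NULL,
                                  loc_error_sd = 0.035,
                                  bleach_rate = 0, pixel_size = 0.1,
                                  fov = c(128, 128), seed) {
  stopifnot(length(fractions) == 3, abs(sum(fractions) - 1) < 1e-9,
            all(fractions >= 0), length(D) == 3, !is.unsorted(D),
            loc_error_sd >= 0, bleach_rate >= 0, frame_interval > 0,
            n_frames >= 1)
  if (!is.null(switch_rates)) {
    stopifnot(is.matrix(switch_rates), all(dim(switch_rates) == c(3, 3)),
              all(switch_rates[upper.tri(switch_rates) |
                               lower.tri(switch_rates)] >= 0))
  }
  dt <- frame_interval
  lim <- fov * pixel_size
  with_seed(seed, {
    states0 <- sample.int(3, n_molecules, replace = TRUE, prob = fractions)
    # geometric track length from per-frame survival exp(-k_b * dt)
    p_bleach <- 1 - exp(-bleach_rate * dt)
    lens <- if (p_bleach > 0) {
      pmin(stats::rgeom(n_molecules, p_bleach) + 1L, n_frames)
    } else rep(n_frames, n_molecules)

    rows <- vector("list", n_molecules)
    states_list <- vector("list", n_molecules)
    for (i in seq_len(n_molecules)) {
      L <- lens[i]
      st <- integer(L)
      st[1] <- states0[i]
      if (is.null(switch_rates)) {
        st[] <- states0[i]
        var_step <- rep(2 * D[states0[i]] * dt, max(L - 1L, 0L))
      } else {
        # continuous-time state path; per-frame variance integrates D
        var_step <- numeric(max(L - 1L, 0L))
        cur <- states0[i]
        t_in_frame <- 0
        frame <- 1L
        acc <- 0
        while (frame < L) {
          rate <- sum(switch_rates[cur, -cur])
          wait <- if (rate > 0) stats::rexp(1, rate) else Inf
          remaining <- dt - t_in_frame
          if (wait >= remaining) {
            acc <- acc + 2 * D[cur] * remaining
            var_step[frame] <- acc
            st[frame + 1L] <- cur
            frame <- frame + 1L
            t_in_frame <- 0
            acc <- 0
            if (is.finite(wait)) {
              # waiting time is memoryless; resample next frame
            }
          } else {
            acc <- acc + 2 * D[cur] * wait
            t_in_frame <- t_in_frame + wait
            probs <- switch_rates[cur, ]
            probs[cur] <- 0
            cur <- sample.int(3, 1, prob = probs)
          }
        }
      }
      x <- numeric(L)
      y <- numeric(L)
      x[1] <- stats::runif(1, 0.1 * lim[1], 0.9 * lim[1])
      y[1] <- stats::runif(1, 0.1 * lim[2], 0.9 * lim[2])
      if (L > 1) {
        sdv <- sqrt(var_step)
        x[-1] <- x[1] + cumsum(stats::rnorm(L - 1L, 0, sdv))
        y[-1] <- y[1] + cumsum(stats::rnorm(L - 1L, 0, sdv))
      }
      # leaving the field of view terminates the track
      out_fov <- which(x < 0 | x > lim[1] | y < 0 | y > lim[2])
      if (length(out_fov)) {
        L <- out_fov[1] - 1L
        if (L < 1) next
        x <- x[seq_len(L)]; y <- y[seq_len(L)]; st <- st[seq_len(L)]
      }
      obs_x <- x + stats::rnorm(L, 0, loc_error_sd)
      obs_y <- y + stats::rnorm(L, 0, loc_error_sd)
      rows[[i]] <- data.frame(track_id = i, frame = seq_len(L),
                              x = obs_x, y = obs_y)
      states_list[[i]] <- st
    }
    tracks <- do.call(rbind, rows)
    keep <- which(!vapply(rows, is.null, logical(1)))
    out <- smt_tracks(tracks, frame_interval = dt, pixel_size = pixel_size)
    attr(out, "truth") <- data.frame(track_id = keep, state = states0[keep])
    attr(out, "truth_states") <- states_list[keep]
    out
  })
}

#' Construct an smt_tracks table
#'
#' Canonical trajectory container: one row per localization with columns
#' `track_id`, `frame`, `x`, `y` (um), frames strictly increasing within a
#' track, plus acquisition metadata as attributes.
#'
#' @param df data.frame with columns `track_id`, `frame`, `x`, `y`.
#' @param frame_interval frame interval in s.
#' @param pixel_size um per pixel.
#' @return The classed data.frame.
#' @export
smt_tracks <- function(df, frame_interval, pixel_size = 0.1) {
  stopifnot(all(c("track_id", "frame", "x", "y") %in% names(df)),
            frame_interval > 0)
  df <- df[order(df$track_id, df$frame), , drop = FALSE]
  rownames(df) <- NULL
  bad <- unlist(lapply(split(df$frame, df$track_id),
                       function(f) any(diff(f) <= 0)))
  if (any(bad)) stop("frames must be strictly increasing within a track")
  structure(df, frame_interval = frame_interval, pixel_size = pixel_size,
            class = c("smt_tracks", "data.frame"))
}

#' Split an smt_tracks table into per-track data.frames
#' @param tracks an `smt_tracks` object.
#' @return Named list of per-track data.frames (columns `frame`,`x`,`y`).
#' @export
split_tracks <- function(tracks) {
  split(as.data.frame(tracks)[c("frame", "x", "y")], tracks$track_id)
}

#' Write / read trajectory tables as CSV
#'
#' Column schema: `track_id, frame, x_um, y_um`; acquisition metadata
#' travels in a JSON sidecar written next to the CSV.
#'
#' @param tracks an `smt_tracks` object.
#' @param path CSV path.
#' @return `path` (write) or an `smt_tracks` object (read).
#' @export
write_tracks_csv <- function(tracks, path) {
  df <- data.frame(track_id = tracks$track_id, frame = tracks$frame,
                   x_um = tracks$x, y_um = tracks$y)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(frame_interval = attr(tracks, "frame_interval"),
               pixel_size = attr(tracks, "pixel_size"))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_tracks_csv
#' @param frame_interval,pixel_size used when no metadata sidecar exists.
#' @export
read_tracks_csv <- function(path, frame_interval = NULL, pixel_size = 0.1) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path)
    frame_interval <- frame_interval %||% meta$frame_interval
    pixel_size <- meta$pixel_size %||% pixel_size
  }
  if (is.null(frame_interval)) stop("frame_interval not given and no sidecar")
  smt_tracks(data.frame(track_id = df$track_id, frame = df$frame,
                        x = df$x_um, y = df$y_um),
             frame_interval = frame_interval, pixel_size = pixel_size)
}

#' Render trajectories into a synthetic image stack
#'
#' Each localization becomes a 2D Gaussian spot of total intensity
#' `photons` (integrated) sampled at pixel centres, on a uniform
#' background; every pixel is then Poisson shot-noise sampled. Pixel (i,j)
#' covers `[i-1,i) x [j-1,j)` in pixel units with centre at `i-0.5`.
#'
#' @param tracks an `smt_tracks` object (positions in um).
#' @param psf_sd PSF Gaussian SD in um.
#' @param photons expected photons per spot (>= 0).
#' @param background expected background photons per pixel (>= 0).
#' @param fov stack size in pixels (width, height).
#' @param n_frames number of frames; defaults to the maximum track frame.
#' @param seed integer seed for the Poisson noise.
#' @return Integer array `[frame, row(y), col(x)]` of photon counts.
#' @export
render_image_stack <- function(tracks, psf_sd = 0.135, photons = 500,
                               background = 10, fov = c(64, 64),
                               n_frames = NULL, seed) {
  if (photons < 0 || background < 0) {
    stop("photons and background must be non-negative")
  }
  px <- attr(tracks, "pixel_size") %||% 0.1
  n_frames <- n_frames %||% max(tracks$frame)
  W <- fov[1]; H <- fov[2]
  if (any(tracks$x < 0 | tracks$x > W * px |
          tracks$y < 0 | tracks$y > H * px)) {
    stop("trajectories do not fit inside the field of view")
  }
  s <- psf_sd / px
  xc <- seq_len(W) - 0.5
  yc <- seq_len(H) - 0.5
  with_seed(seed, {
    stack <- array(0, dim = c(n_frames, H, W))
    for (t in seq_len(n_frames)) {
      img <- matrix(background, H, W)
      sel <- which(tracks$frame == t)
      for (k in sel) {
        gx <- exp(-(xc - tracks$x[k] / px)^2 / (2 * s^2))
        gy <- exp(-(yc - tracks$y[k] / px)^2 / (2 * s^2))
        img <- img + photons * (gy %o% gx) / (2 * pi * s^2)
      }
      stack[t, , ] <- matrix(stats::rpois(H * W, img), H, W)
    }
    stack
  })
}

#' Write an image stack as multi-page 16-bit grayscale TIFF
#' @param stack array `[frame, row, col]` of counts.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required to write TIFF stacks")
  }
  pages <- lapply(seq_len(dim(stack)[1]), function(t) {
    m <- stack[t, , ] / 65535
    m[m > 1] <- 1
    m
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}

#' Simulate residence times from a bi-exponential dwell mixture
#'
#' Residence times are drawn from
#' `frac_long * Exp(1/tau_long) + (1-frac_long) * Exp(1/tau_short)`,
#' quantized upward to whole frames (a molecule present for any part of a
#' frame occupies it) and right-censored at the acquisition limit.
#'
#' @param tau_long,tau_short mean dwell times in s (`tau_long > tau_short`).
#' @param frac_long mixture weight of the long-lived component.
#' @param n_tracks number of residence times.
#' @param frame_interval frame interval in s (slow modality: 0.5).
#' @param censor_at acquisition limit in s (>= frame_interval).
#' @param seed integer seed.
#' @return Numeric vector of quantized, censored residence times with
#'   attributes `raw` (pre-quantization draws) and `component`
#'   (TRUE = long-lived).
#' @export
simulate_dwell_data <- function(tau_long = 5, tau_short = 0.9,
                                frac_long = 0.5, n_tracks = 2000,
                                frame_interval = 0.5, censor_at = 250,
                                seed) {
  stopifnot(tau_long > tau_short, tau_short > 0,
            frac_long >= 0, frac_long <= 1, n_tracks >= 1)
  if (censor_at < frame_interval) {
    stop("censor_at must be >= frame_interval")
  }
  with_seed(seed, {
    is_long <- stats::runif(n_tracks) < frac_long
    raw <- ifelse(is_long, stats::rexp(n_tracks, 1 / tau_long),
                  stats::rexp(n_tracks, 1 / tau_short))
    quant <- ceiling(raw / frame_interval) * frame_interval
    censored <- pmin(quant, floor(censor_at / frame_interval) * frame_interval)
    structure(censored, raw = raw, component = is_long)
  })
}

#' Simulate two-time-point yeast-two-hybrid fluorescence readings
#'
#' Interaction strength drives growth between the two time points:
#' `f_t2 = f_t1 * growth * strength` (log-normal measurement noise on
#' both readings), so the T2/T1 ratio normalised to the WT bait recovers
#' the relative strength.
#'
#' @param strengths data.frame with columns `bait`, `prey`, `strength`
#'   (relative to WT = 1).
#' @param n_replicates replicates per pair.
#' @param t1_mean mean T1 fluorescence (a.u.).
#' @param growth T2/T1 growth factor at strength 1.
#' @param noise_cv coefficient of variation of the log-normal noise.
#' @param seed integer seed.
#' @return data.frame (`bait`, `prey`, `replicate`, `f_t1`, `f_t2`).
#' @export
simulate_y2h <- function(strengths, n_replicates = 3, t1_mean = 1000,
                         growth = 4, noise_cv = 0.05, seed) {
  stopifnot(all(c("bait", "prey", "strength") %in% names(strengths)),
            all(strengths$strength >= 0))
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(strengths)), function(i) {
      ln_sd <- sqrt(log(1 + noise_cv^2))
      f1 <- t1_mean * exp(stats::rnorm(n_replicates, -ln_sd^2 / 2, ln_sd))
      f2 <- f1 * growth * strengths$strength[i] *
        exp(stats::rnorm(n_replicates, -ln_sd^2 / 2, ln_sd))
      data.frame(bait = strengths$bait[i], prey = strengths$prey[i],
                 replicate = seq_len(n_replicates), f_t1 = f1, f_t2 = f2,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
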