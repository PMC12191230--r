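# shift-and-add 2D convolution with a small square kernel, "same" size,
# zero-padded borders
conv2_same <- function(img, kern) {
  kh <- nrow(kern); kw <- ncol(kern)
  oh <- (kh - 1L) %/% 2L; ow <- (kw - 1L) %/% 2L
  H <- nrow(img); W <- ncol(img)
  out <- matrix(0, H, W)
  for (a in seq_len(kh)) {
    for (b in seq_len(kw)) {
      w <- kern[a, b]
      if (w == 0) next
      dy <- a - 1L - oh; dx <- b - 1L - ow
      ys <- max(1, 1 - dy):min(H, H - dy)
      xs <- max(1, 1 - dx):min(W, W - dx)
      out[ys, xs] <- out[ys, xs] + w * img[ys + dy, xs + dx]
    }
  }
  out
}

gauss_kernel <- function(box, sd_px) {
  half <- (box - 1) / 2
  g1 <- exp(-((-half:half)^2) / (2 * sd_px^2))
  g1 %o% g1
}

#' Detect diffraction-limited spots in one frame
#'
#' Two-step detection in the spirit of multiple-target tracing: (1) a
#' generalized-likelihood-ratio test of a Gaussian spot of known PSF width
#' versus flat background in a `box` x `box` window — the matched-filter
#' amplitude estimate is compared against the global robust noise level at
#' the false-alarm probability `pfa`, keeping local maxima whose amplitude
#' also exceeds `threshold` times the noise; (2) least-squares 2D Gaussian
#' refinement of each candidate (amplitude, background, subpixel centre),
#' rejecting fits that move more than `max_refine` pixels or fail to
#' converge. Pixel `(i, j)` has centre `(j - 0.5, i - 0.5)` in pixel
#' units, so returned coordinates are directly scalable by the pixel size.
#'
#' @param frame_image 2D non-negative numeric matrix (photon counts).
#' @param psf_sd PSF Gaussian SD in pixels.
#' @param pfa per-pixel false-alarm probability (default `10^-6.5`).
#' @param threshold candidate-seeding factor on the matched-filter
#'   amplitude relative to the noise SD (default 1.5).
#' @param box detection window size in pixels (odd; default 7).
#' @param max_iter,tol refinement iteration cap and termination tolerance.
#' @param max_refine maximum allowed refinement displacement in pixels.
#' @return data.frame (`x`, `y` subpixel pixel units, `intensity` fitted
#'   amplitude, `converged` logical).
#' @export
detect_spots <- function(frame_image, psf_sd = 1.35, pfa = 10^-6.5,
                         threshold = 1.5, box = 7, max_iter = 50,
                         tol = 1e-2, max_refine = 1.5) {
  H <- nrow(frame_image); W <- ncol(frame_image)
  if (H < box || W < box) stop("image smaller than the detection box")
  g <- gauss_kernel(box, psf_sd)
  g0 <- g - mean(g)
  S <- sum(g0^2)
  # LS amplitude of a PSF-shaped spot at every pixel (flat-background GLRT)
  conv_g <- conv2_same(frame_image, g)
  conv_1 <- conv2_same(frame_image, matrix(1, box, box))
  amp <- (conv_g - mean(g) * conv_1) / S
  sigma_n <- stats::mad(as.vector(frame_image))
  if (sigma_n == 0) sigma_n <- stats::sd(as.vector(frame_image))
  if (is.na(sigma_n) || sigma_n == 0) return(empty_spots())
  z <- amp * sqrt(S) / sigma_n
  z_crit <- stats::qnorm(1 - pfa)

  half <- (box - 1) %/% 2
  cand <- which(z > z_crit & amp > threshold * sigma_n, arr.ind = TRUE)
  # interior only: refinement window must fit
  cand <- cand[cand[, 1] > half & cand[, 1] <= H - half &
               cand[, 2] > half & cand[, 2] <= W - half, , drop = FALSE]
  # local maxima of the test statistic within a 3x3 neighbourhood
  is_max <- vapply(seq_len(nrow(cand)), function(k) {
    i <- cand[k, 1]; j <- cand[k, 2]
    z[i, j] >= max(z[max(1, i - 1):min(H, i + 1),
                     max(1, j - 1):min(W, j + 1)])
  }, logical(1))
  cand <- cand[is_max, , drop = FALSE]
  if (nrow(cand) == 0) return(empty_spots())

  res <- lapply(seq_len(nrow(cand)), function(k) {
    i <- cand[k, 1]; j <- cand[k, 2]
    win <- frame_image[(i - half):(i + half), (j - half):(j + half)]
    fit <- refine_gaussian(win, psf_sd, max_iter, tol)
    dx <- fit$x - (half + 0.5); dy <- fit$y - (half + 0.5)
    if (!fit$converged || fit$amp <= 0 ||
        sqrt(dx^2 + dy^2) > max_refine) return(NULL)
    data.frame(x = (j - 0.5) + dx, y = (i - 0.5) + dy,
               intensity = fit$amp, converged = TRUE)
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (length(res) == 0) return(empty_spots())
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

empty_spots <- function() {
  data.frame(x = numeric(0), y = numeric(0), intensity = numeric(0),
             converged = logical(0))
}

# least-squares 2D Gaussian (fixed width) on a square window; coordinates
# within the window, pixel centres at integer - 0.5
refine_gaussian <- function(win, psf_sd, max_iter, tol) {
  b <- nrow(win)
  xc <- seq_len(b) - 0.5
  grid_x <- matrix(rep(xc, each = b), b, b)   # column coord
  grid_y <- matrix(rep(xc, times = b), b, b)  # row coord
  model <- function(p) {
    p[4] + p[3] * exp(-((grid_x - p[1])^2 + (grid_y - p[2])^2) /
                        (2 * psf_sd^2))
  }
  start <- c(x = b / 2, y = b / 2,
             amp = max(win) - stats::median(win), bg = stats::median(win))
  fit <- tryCatch(
    suppressWarnings(minpack.lm::nls.lm(
      par = start,
      fn = function(p) as.vector(win - model(p)),
      control = minpack.lm::nls.lm.control(maxiter = max_iter,
                                           ftol = tol * 1e-6,
                                           ptol = tol * 1e-4)
    )),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(list(x = b / 2, y = b / 2, amp = 0, converged = FALSE))
  }
  p <- fit$par
  list(x = p[["x"]], y = p[["y"]], amp = p[["amp"]],
       converged = fit$info %in% 1:4)
}

#' Detect spots across a full image stack
#'
#' @param stack array `[frame, row, col]`.
#' @param pixel_size um per pixel (default 0.1).
#' @inheritParams detect_spots
#' @return data.frame (`frame`, `x`, `y` in um, `intensity`).
#' @export
detect_stack <- function(stack, psf_sd = 1.35, pfa = 10^-6.5,
                         threshold = 1.5, box = 7, max_iter = 50,
                         tol = 1e-2, max_refine = 1.5, pixel_size = 0.1) {
  out <- lapply(seq_len(dim(stack)[1]), function(t) {
    d <- detect_spots(stack[t, , ], psf_sd, pfa, threshold, box,
                      max_iter, tol, max_refine)
    if (nrow(d) == 0) return(NULL)
    data.frame(frame = t, x = d$x * pixel_size, y = d$y * pixel_size,
               intensity = d$intensity)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) {
    return(data.frame(frame = integer(0), x = numeric(0), y = numeric(0),
                      intensity = numeric(0)))
  }
  do.call(rbind, out)
}

#' Link localizations into trajectories by greedy nearest neighbour
#'
#' Localizations in successive frames are linked when closer than the
#' tracking radius; links are assigned greedily in order of ascending
#' distance with one-to-one enforcement, so of two candidates inside the
#' radius of one track end the nearer wins and the other starts a new
#' track. A track end may persist unmatched through up to `max_gap` frames
#' (gap closing) before the track is closed. Tracks shorter than
#' `min_length` localizations are discarded.
#'
#' The search radius is `radius` pixels times the pixel size; when the
#' modality's maximum expected diffusion coefficient `d_max` is supplied,
#' the radius is capped at the Rayleigh 99.9th-percentile displacement
#' `sqrt(4 * d_max * dt * ln 1000)` for the frame interval.
#'
#' @param locs data.frame (`frame`, `x`, `y` in um).
#' @param frame_interval frame interval in s.
#' @param radius tracking radius in pixels (default 9).
#' @param pixel_size um per pixel (default 0.1).
#' @param max_gap maximum gap frames bridged (default 2).
#' @param min_length minimum localizations per track (default 5).
#' @param d_max optional maximum expected diffusion coefficient (um^2/s).
#' @return An `smt_tracks` object.
#' @export
link_trajectories <- function(locs, frame_interval, radius = 9,
                              pixel_size = 0.1, max_gap = 2,
                              min_length = 5, d_max = NULL) {
  stopifnot(radius > 0, max_gap >= 0, min_length >= 2)
  if (anyDuplicated(locs[c("frame", "x", "y")])) {
    stop("duplicate localizations at identical (frame, x, y)")
  }
  r_um <- radius * pixel_size
  if (!is.null(d_max)) {
    r_um <- min(r_um, sqrt(4 * d_max * frame_interval * log(1000)))
  }
  locs <- locs[order(locs$frame), , drop = FALSE]
  if (nrow(locs) == 0) {
    return(smt_tracks(data.frame(track_id = integer(0), frame = integer(0),
                                 x = numeric(0), y = numeric(0)),
                      frame_interval, pixel_size))
  }
  # active track state: position/frame of each open track end
  track_rows <- list()
  open_id <- integer(0); open_x <- numeric(0); open_y <- numeric(0)
  open_f <- integer(0)
  next_id <- 1L
  for (f in seq(min(locs$frame), max(locs$frame))) {
    # close track ends that exceeded the gap allowance
    expired <- open_f < f - (max_gap + 1L)
    open_id <- open_id[!expired]; open_x <- open_x[!expired]
    open_y <- open_y[!expired]; open_f <- open_f[!expired]
    cur <- locs[locs$frame == f, , drop = FALSE]
    if (nrow(cur) == 0) next
    assigned <- rep(FALSE, nrow(cur))
    if (length(open_id) > 0) {
      dmat <- sqrt(outer(open_x, cur$x, "-")^2 +
                   outer(open_y, cur$y, "-")^2)
      dmat[dmat > r_um] <- NA
      repeat {
        if (all(is.na(dmat))) break
        best <- which(dmat == min(dmat, na.rm = TRUE), arr.ind = TRUE)[1, ]
        ti <- best[1]; ci <- best[2]
        id <- open_id[ti]
        track_rows[[id]] <- rbind(track_rows[[id]],
                                  data.frame(track_id = id, frame = f,
                                             x = cur$x[ci], y = cur$y[ci]))
        open_x[ti] <- cur$x[ci]; open_y[ti] <- cur$y[ci]; open_f[ti] <- f
        assigned[ci] <- TRUE
        dmat[ti, ] <- NA
        dmat[, ci] <- NA
      }
    }
    for (ci in which(!assigned)) {
      id <- next_id
      next_id <- next_id + 1L
      track_rows[[id]] <- data.frame(track_id = id, frame = f,
                                     x = cur$x[ci], y = cur$y[ci])
      open_id <- c(open_id, id)
      open_x <- c(open_x, cur$x[ci]); open_y <- c(open_y, cur$y[ci])
      open_f <- c(open_f, f)
    }
  }
  keep <- vapply(track_rows, nrow, integer(1)) >= min_length
  kept <- track_rows[keep]
  if (length(kept) == 0) {
    return(smt_tracks(data.frame(track_id = integer(0), frame = integer(0),
                                 x = numeric(0), y = numeric(0)),
                      frame_interval, pixel_size))
  }
  df <- do.call(rbind, kept)
  # renumber consecutively
  df$track_id <- match(df$track_id, unique(df$track_id))
  smt_tracks(df, frame_interval, pixel_size)
}
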