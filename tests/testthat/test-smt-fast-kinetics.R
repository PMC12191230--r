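test_that("MSD plateaus at 4 sigma^2 for an immobile noisy molecule", {
  set.seed(41)
  sigma <- 0.035
  traj <- data.frame(frame = 1:4000, x = rnorm(4000, 0, sigma),
                     y = rnorm(4000, 0, sigma))
  curve <- msd_curve(traj, 0.02, fraction_used = 0.01)
  expect_true(all(abs(curve$msd - 4 * sigma^2) / (4 * sigma^2) < 0.1))
})

test_that("MSD of deterministic linear motion is quadratic in lag", {
  v <- 0.3  # um per frame
  traj <- data.frame(frame = 1:30, x = v * (1:30), y = 0)
  curve <- msd_curve(traj, 1)
  expect_equal(curve$msd, (v * curve$lag)^2, tolerance = 1e-12)
})

test_that("MSD of Brownian simulation follows 4 D t + 4 sigma^2", {
  tr <- simulate_trajectories(400, fractions = c(0, 0, 1),
                              D = c(0.01, 0.1, 0.5), loc_error_sd = 0.03,
                              n_frames = 40, fov = c(512, 512), seed = 44)
  curves <- lapply(split_tracks(tr), msd_curve, frame_interval = 0.02)
  lag1 <- vapply(curves, function(cv) cv$msd[1], numeric(1))
  expected <- 4 * 0.5 * 0.02 + 4 * 0.03^2
  expect_lt(abs(mean(lag1) - expected) / expected, 0.05)
})

test_that("power-law MSD fits invert noiseless curves", {
  t <- (1:20) * 0.02
  fit1 <- fit_msd_powerlaw(data.frame(lag = t, msd = 4 * 0.2 * t))
  expect_equal(fit1$D_app, 0.2, tolerance = 1e-4)
  expect_equal(fit1$alpha, 1, tolerance = 1e-3)
  fit2 <- fit_msd_powerlaw(data.frame(lag = t, msd = 4 * 0.2 * t^0.5))
  expect_equal(fit2$alpha, 0.5, tolerance = 1e-3)
})

test_that("per-track diffusion matches closed forms and recovers simulations", {
  frozen <- data.frame(frame = 1:10, x = rep(1, 10), y = rep(2, 10))
  expect_equal(per_track_diffusion(frozen, 0.02, 0), 1e-6)
  # constant jump r per frame
  r <- 0.2
  lin <- data.frame(frame = 1:10, x = r * (1:10), y = 0)
  expect_equal(per_track_diffusion(lin, 0.02, 0.01),
               r^2 / (4 * 0.02) - 0.01^2 / 0.02, tolerance = 1e-12)
  # simulated single state, known sigma
  tr <- simulate_trajectories(600, fractions = c(0, 1, 0),
                              D = c(0.01, 0.15, 1), loc_error_sd = 0.035,
                              n_frames = 30, fov = c(512, 512), seed = 48)
  Ds <- vapply(split_tracks(tr), per_track_diffusion, numeric(1),
               frame_interval = 0.02, sigma_est = 0.035)
  expect_lt(abs(median(Ds) - 0.15) / 0.15, 0.15)
})

test_that("mobile/immobile split behaves at the threshold and on mixtures", {
  expect_equal(split_mobile_immobile(rep(0.01, 5))[["immobile_fraction"]], 1)
  v <- c(0.01, 0.02, 0.5, 0.9)
  s <- split_mobile_immobile(v, d_threshold = median(v))
  expect_equal(unname(s["mobile_fraction"] + s["immobile_fraction"]), 1)
  tr <- simulate_trajectories(1500, fractions = c(0.3, 0.2, 0.5),
                              D = c(0.005, 0.3, 1.2), loc_error_sd = 0.035,
                              n_frames = 25, fov = c(512, 512), seed = 52)
  Ds <- vapply(split_tracks(tr), per_track_diffusion, numeric(1),
               frame_interval = 0.02, sigma_est = 0.035)
  s2 <- split_mobile_immobile(Ds)
  expect_lt(abs(s2[["immobile_fraction"]] - 0.3), 0.05)
})

test_that("three-state fit recovers a degenerate single-state simulation", {
  tr <- simulate_trajectories(1500, fractions = c(1, 0, 0),
                              D = c(0.01, 0.15, 1), loc_error_sd = 0.035,
                              n_frames = 20, seed = 61)
  fit <- fit_three_state(tr, seed = 1)
  expect_gte(fit$F[["bound"]], 0.95)
  expect_lt(abs(fit$sigma - 0.035) / 0.035, 0.2)
  expect_equal(sum(fit$F), 1, tolerance = 1e-6)
})

test_that("three-state fit respects bounds, simplex, and multi-start SSE", {
  tr <- simulate_trajectories(2000, fractions = c(0.3, 0.3, 0.4),
                              D = c(0.01, 0.15, 1.0), loc_error_sd = 0.035,
                              n_frames = 15, bleach_rate = 5,
                              fov = c(256, 256), seed = 62)
  fit <- fit_three_state(tr, seed = 3)
  expect_equal(sum(fit$F), 1, tolerance = 1e-6)
  expect_true(fit$D[["bound"]] >= 1e-5 && fit$D[["bound"]] <= 0.1)
  expect_true(fit$D[["slow"]] >= 1e-3 && fit$D[["slow"]] <= 0.5)
  expect_true(fit$D[["fast"]] >= 0.2 && fit$D[["fast"]] <= 5)
  expect_equal(fit$sse, min(fit$all_sse))
  expect_error(fit_three_state(simulate_trajectories(3, n_frames = 10,
                                                     seed = 1)),
               "500")
})

test_that("jump angles fold correctly for straight and zigzag motion", {
  expect_true(all(jump_angles(straight_track()) < 1e-9))
  expect_true(all(abs(jump_angles(zigzag_track()) - 180) < 1e-9))
  # below-threshold jumps are excluded
  expect_equal(length(jump_angles(straight_track(step = 0.05))), 0)
})

test_that("Brownian jump angles are isotropic; traps induce reversals", {
  tr <- simulate_trajectories(400, fractions = c(0, 0, 1),
                              D = c(0.01, 0.1, 0.8), loc_error_sd = 0,
                              n_frames = 30, fov = c(512, 512), seed = 71)
  ang <- unlist(lapply(split_tracks(tr), jump_angles), use.names = FALSE)
  expect_gt(length(ang), 3000)
  ks <- suppressWarnings(ks.test(ang, "punif", 0, 180))
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(anisotropy(ang) - 1), 0.1)
  # localization error alone induces apparent reversals (anisotropy > 1)
  trn <- simulate_trajectories(400, fractions = c(0, 0, 1),
                               D = c(0.01, 0.1, 0.35), loc_error_sd = 0.05,
                               n_frames = 30, fov = c(512, 512), seed = 72)
  angn <- unlist(lapply(split_tracks(trn), jump_angles), use.names = FALSE)
  expect_gt(anisotropy(angn), 1.1)
  # zigzag: empty forward window flagged as +Inf
  az <- anisotropy(jump_angles(zigzag_track()))
  expect_true(is.infinite(az))
  expect_equal(attr(az, "flag"), "empty_forward")
})

test_that("confinement radius matches geometry and grows with track length", {
  same <- data.frame(frame = 1:6, x = rep(1, 6), y = rep(1, 6))
  expect_equal(confinement_radius(same), 0)
  sq <- data.frame(frame = 1:5,
                   x = c(0, 0.2, 0.2, 0, 0.1), y = c(0, 0, 0.2, 0.2, 0.1))
  # 4 corners of a 0.2 um square (plus centre point, which is the centroid)
  expect_equal(confinement_radius(sq), 0.1 * sqrt(2), tolerance = 1e-9)
  expect_lt(confinement_radius(sq, method = "gyration"),
            confinement_radius(sq))
  # immobile molecules: modal radius grows with track length
  set.seed(3)
  radius_at <- function(L) {
    median(replicate(200, {
      confinement_radius(data.frame(frame = 1:L, x = rnorm(L, 0, 0.035),
                                    y = rnorm(L, 0, 0.035)))
    }))
  }
  expect_lt(radius_at(6), radius_at(60))
})

test_that("per-cell features separate planted cell populations in PCA", {
  slow_cells <- lapply(1:4, function(i) {
    simulate_trajectories(150, fractions = c(1, 0, 0), D = c(0.01, 0.1, 1),
                          n_frames = 20, seed = 100 + i)
  })
  fast_cells <- lapply(1:4, function(i) {
    simulate_trajectories(150, fractions = c(0, 0, 1), D = c(0.01, 0.1, 1),
                          n_frames = 20, fov = c(512, 512), seed = 200 + i)
  })
  feats <- do.call(rbind, c(
    lapply(seq_along(slow_cells), function(i) {
      cell_features(slow_cells[[i]], cell_id = paste0("bound_", i))
    }),
    lapply(seq_along(fast_cells), function(i) {
      cell_features(fast_cells[[i]], cell_id = paste0("fast_", i))
    })
  ))
  pca <- suppressWarnings(features_pca(feats))
  pc1 <- pca$scores[, 1]
  disjoint <- max(pc1[1:4]) < min(pc1[5:8]) || max(pc1[5:8]) < min(pc1[1:4])
  expect_true(disjoint)
  expect_lte(sum(pca$explained_variance), 1 + 1e-9)
  # identical cells: PCA degenerates to the origin
  same <- feats[c(1, 1, 1), ]
  pca0 <- suppressWarnings(features_pca(same))
  expect_true(all(pca0$scores == 0))
})
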