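# Tracking, immobile removal, bleach extrapolation, registration, cotracking,
# segmentation and the density equations

test_that("well-separated molecules give complete, distinct tracks", {
  tab <- data.frame(frame = rep(0:19, 2),
                    x_um = c(rep(1, 20) + 0.01 * (0:19),
                             rep(8, 20) + 0.01 * (0:19)),
                    y_um = rep(c(1, 8), each = 20),
                    channel = "ch1")
  tr <- link_tracks(tab, quant_config())
  expect_equal(length(unique(tr$track_id)), 2L)
  expect_equal(unname(table(tr$track_id)), c(20L, 20L), ignore_attr = TRUE)
})

test_that("gap closing bridges a single missed frame", {
  tab <- data.frame(frame = c(0:4, 6:10), x_um = 1 + 0.01 * c(0:4, 6:10),
                    y_um = 2, channel = "ch1")
  tr1 <- link_tracks(tab, quant_config(max_gap = 1))
  expect_equal(length(unique(tr1$track_id)), 1L)
  tr0 <- link_tracks(tab, quant_config(max_gap = 0))
  expect_equal(length(unique(tr0$track_id)), 2L)
})

test_that("tracker recovers ground-truth trajectories exactly on noiseless data", {
  sim <- simulate_smlm(sim_config(true_density = 0.05, field = c(15, 15),
                                  diffusion_coeff = 0.02, bleach_prob = 0.01,
                                  detection_prob = 1, localization_sigma = 0,
                                  seed = 6))
  tr <- link_tracks(sim$table, quant_config())
  # every reconstructed track contains exactly one ground-truth molecule, and
  # every molecule is recovered as one full track
  grp <- split(tr$molecule_id, tr$track_id)
  expect_true(all(vapply(grp, function(g) length(unique(g)) == 1, logical(1))))
  per_mol <- table(sim$table$molecule_id)
  got <- vapply(grp, length, integer(1))
  expect_equal(sort(unname(got)), sort(unname(as.integer(per_mol))))
  expect_equal(length(grp), length(per_mol))
})

test_that("stationary tracks are immobile; Brownian tracks stay mobile", {
  still <- data.frame(track_id = 1L, frame = 0:49, x_um = 2, y_um = 2)
  class(still) <- c("track_set", "data.frame")
  out <- remove_immobile(still, quant_config())
  expect_equal(nrow(out), 0L)
  expect_equal(attr(out, "n_immobile"), 1L)

  # D = 0.1 um^2/s tracks against a 0.05 um radius: < 5% misclassified
  set.seed(8)
  dt <- 0.032
  tracks <- do.call(rbind, lapply(1:100, function(id) {
    n <- 50
    data.frame(track_id = id,
               frame = 0:(n - 1),
               x_um = cumsum(c(5, rnorm(n - 1, 0, sqrt(2 * 0.1 * dt)))),
               y_um = cumsum(c(5, rnorm(n - 1, 0, sqrt(2 * 0.1 * dt)))))
  }))
  class(tracks) <- c("track_set", "data.frame")
  mob <- remove_immobile(tracks, quant_config(immobile_radius = 0.05))
  expect_gte(attr(mob, "n_mobile"), 95L)
})

test_that("immobile background is removed at the simulated rate", {
  res <- vapply(1:20, function(s) {
    sim <- simulate_smlm(sim_config(true_density = 0.2,
                                    immobile_density = 0.2,
                                    field = c(12, 12), diffusion_coeff = 0.1,
                                    bleach_prob = 0.02, detection_prob = 0.9,
                                    seed = s))
    tr <- link_tracks(sim$table, quant_config())
    mob <- remove_immobile(tr, quant_config())
    c(removed = attr(mob, "n_immobile"), truth = sim$truth$n_immobile)
  }, numeric(2))
  diffs <- res["removed", ] - res["truth", ]
  se <- stats::sd(diffs) / sqrt(ncol(res))
  # mobile molecules that bleach within their first frames leave tracks too
  # short to show motion; they are indistinguishable from adsorbed background
  # and produce a small positive excess (~ n_mobile * P(bleach <= 2 frames))
  expect_gt(mean(diffs), -3 * se)
  expect_lt(mean(diffs), 0.1 * mean(res["truth", ]) + 3 * se)
})

test_that("bleach extrapolation recovers exact, constant and invalid series", {
  t <- 0:99
  exact <- estimate_initial_count(100 * exp(-0.05 * t))
  expect_equal(exact$N0, 100, tolerance = 1e-6)
  expect_equal(exact$k, 0.05, tolerance = 1e-6)
  expect_warning(flat <- estimate_initial_count(rep(50, 20)),
                 "non-decreasing")
  expect_equal(flat$N0, 50)
  expect_equal(flat$k, 0)
  expect_equal(flat$flag, "non_decreasing")
  expect_error(estimate_initial_count(rep(0, 20)), "all-zero")
  expect_error(estimate_initial_count(c(5, 4, 3)), "at least 10")
})

test_that("surface density and per-cell scaling are exact quotients/products", {
  expect_equal(density_per_um2(80, 100), 0.8)
  expect_equal(density_per_um2(0, 100), 0)
  expect_equal(density_per_um2(80, 200), density_per_um2(80, 100) / 2)
  expect_error(density_per_um2(10, 0), "vCSA")
  expect_equal(per_cell_count(0.8, 3900), 3120)
  expect_equal(per_cell_count(0), 0)
  expect_equal(estimate_tcsa(1950), 3900)
})

test_that("dual-color corrected count follows A + B - 0.5*AB exactly", {
  expect_equal(dual_color_count(120, 100, 40), 200)
  expect_equal(dual_color_count(120, 100, 0), 220)
  expect_equal(dual_color_count(100, 100, 100), 150)
  expect_error(dual_color_count(10, 5, 7), "exceeds")
})

test_that("vCSA segmentation recovers a bright square and rejects flat images", {
  img <- matrix(0, 200, 200)
  img[51:150, 61:160] <- 100
  img <- img + matrix(rnorm(200 * 200, 0, 1), 200, 200)
  a <- segment_vcsa(img, pixel_size = 0.1)
  expect_equal(as.numeric(a), 100, tolerance = 0.02)
  # additive offset leaves the segmented area unchanged
  a2 <- segment_vcsa(img + 37, pixel_size = 0.1)
  expect_equal(as.numeric(a2), as.numeric(a))
  expect_error(segment_vcsa(matrix(0, 50, 50), pixel_size = 0.1),
               "empty foreground")
})

test_that("channel registration: identity, translation, collinear points", {
  set.seed(10)
  pts <- cbind(runif(50, 0, 10), runif(50, 0, 10))
  id <- register_channels(pts, pts)
  expect_equal(id$residual_rms, 0, tolerance = 1e-12)
  expect_equal(id$rotation_deg, 0, tolerance = 1e-9)
  shifted <- sweep(pts, 2, c(0.3, -0.2), "+")
  tr <- register_channels(pts, shifted)
  expect_equal(tr$translation, c(-0.3, 0.2), tolerance = 1e-9)
  expect_equal(tr$apply(shifted), pts, tolerance = 1e-9, ignore_attr = TRUE)
  col <- cbind(1:5, 2 * (1:5))
  expect_error(register_channels(col, col), "collinear")
  expect_error(register_channels(pts[1:2, ], pts[1:2, ]), "at least 3")
})

test_that("misalign then register recovers bead positions below 5 nm RMS", {
  set.seed(12)
  beads <- cbind(runif(120, 0, 12), runif(120, 0, 12))
  tab <- data.frame(frame = 0L, x_um = beads[, 1], y_um = beads[, 2],
                    channel = "ch2")
  mis <- misalign_channels(tab, shift = c(0.08, -0.03), theta_deg = 0.25,
                           scale = 1.002)
  tr <- register_channels(beads, as.matrix(mis[, c("x_um", "y_um")]))
  expect_lt(tr$residual_rms, 0.005)
})

test_that("colocalization is a strict 150 nm cut with a 10-step minimum", {
  mk_pair <- function(sep, nf) {
    a <- data.frame(track_id = 1L, frame = 0:(nf - 1),
                    x_um = 1 + 0.01 * (0:(nf - 1)), y_um = 1)
    b <- a; b$track_id <- 2L; b$x_um <- b$x_um + sep
    class(a) <- class(b) <- c("track_set", "data.frame")
    list(a = a, b = b)
  }
  p <- mk_pair(0.14, 20)
  expect_equal(as.integer(cotrack(p$a, p$b, quant_config())), 1L)
  p <- mk_pair(0.16, 20)
  expect_equal(as.integer(cotrack(p$a, p$b, quant_config())), 0L)
  p <- mk_pair(0.14, 10)  # 9 consecutive steps only
  expect_equal(as.integer(cotrack(p$a, p$b, quant_config())), 0L)
  p <- mk_pair(0.14, 11)  # exactly 10 steps
  expect_equal(as.integer(cotrack(p$a, p$b, quant_config())), 1L)
})

test_that("spot detection: noiseless accuracy, empty frames, recall at SNR 10", {
  tab <- data.frame(frame = 0L, x_um = 5.037, y_um = 4.42)
  mv <- render_movie(tab, psf_sigma = 0.13, pixel_size = 0.1,
                     field = c(10, 10), photons = 2000, background = 10)
  sp <- detect_spots(mv, pixel_size = 0.1)
  expect_equal(nrow(sp), 1L)
  expect_lt(sqrt((sp$x_um - 5.037)^2 + (sp$y_um - 4.42)^2) / 0.1, 0.1)

  empty <- array(10, c(60, 60, 2))
  expect_equal(nrow(detect_spots(empty, pixel_size = 0.1)), 0L)

  set.seed(5)
  pts <- matrix(numeric(0), 0, 2)
  while (nrow(pts) < 20) {
    p <- runif(2, 1, 11)
    if (!nrow(pts) || min(sqrt(colSums((t(pts) - p)^2))) > 1)
      pts <- rbind(pts, p)
  }
  tr <- data.frame(frame = 0L, x_um = pts[, 1], y_um = pts[, 2])
  mv <- render_movie(tr, psf_sigma = 0.13, pixel_size = 0.1,
                     field = c(12, 12), photons = 800, background = 20)
  mv[] <- mv + rnorm(length(mv), 0, 4)
  sp <- detect_spots(mv, pixel_size = 0.1)
  recall <- mean(vapply(seq_len(20), function(i)
    any(sqrt((sp$x_um - tr$x_um[i])^2 + (sp$y_um - tr$y_um[i])^2) < 0.1),
    logical(1)))
  expect_gte(recall, 0.95)
})

test_that("quantify_density enforces the density identities on every run", {
  sim <- simulate_smlm(sim_config(true_density = 0.3, field = c(12, 12),
                                  immobile_density = 0.1, seed = 21))
  res <- quantify_density(sim$table, quant_config(vCSA = 144))
  expect_identical(res$rho, res$N0_mobile / res$vCSA)
  expect_identical(res$per_cell, res$rho * res$tCSA)
  expect_gte(res$N0_mobile, 0)
  expect_error(quantify_density(sim$table, quant_config(vCSA = NULL)), "vCSA")
})

test_that("similarity registration agrees with an independent Procrustes fit", {
  set.seed(15)
  ref <- cbind(runif(40, 0, 10), runif(40, 0, 10))
  th <- 1.2 * pi / 180
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2, byrow = TRUE)
  mov <- sweep(1.003 * ref %*% t(R), 2, c(0.2, -0.1), "+") +
    matrix(rnorm(80, 0, 0.003), 40, 2)
  ours <- register_channels(ref, mov)
  pf <- vegan::procrustes(ref, mov, scale = TRUE, symmetric = FALSE)
  pf_fit <- sweep(pf$scale * mov %*% pf$rotation, 2,
                  as.numeric(pf$translation), "+")
  expect_equal(ours$apply(mov), pf_fit, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(ours$scale, pf$scale, tolerance = 1e-6)
  expect_equal(ours$residual_rms, sqrt(mean(rowSums((pf_fit - ref)^2))),
               tolerance = 1e-6)
})
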