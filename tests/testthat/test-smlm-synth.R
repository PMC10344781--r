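# Synthetic single-molecule data generator

test_that("degenerate config localizes every molecule in all frames", {
  cfg <- sim_config(true_density = 0.4, field = c(5, 5), diffusion_coeff = 0,
                    bleach_prob = 0, detection_prob = 1,
                    localization_sigma = 0, immobile_density = 0,
                    false_positive_rate = 0, seed = 2)
  sim <- simulate_smlm(cfg)
  n <- sim$truth$n_mobile
  expect_equal(nrow(sim$table), n * 150L)
  for (id in seq_len(n)) {
    sub <- sim$table[sim$table$molecule_id == id, ]
    expect_equal(nrow(sub), 150L)
    expect_equal(length(unique(sub$x_um)), 1L)  # fixed position
  }
})

test_that("molecule numbers are Poisson with the configured density", {
  counts <- vapply(1:100, function(s) {
    sim <- simulate_smlm(sim_config(true_density = 0.8, field = c(5, 5),
                                    n_frames = 2, seed = s))
    sim$truth$n_mobile
  }, numeric(1))
  expected <- 0.8 * 25
  se <- sqrt(expected / 100)
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("dual-color tag assignment gives 50% mixed-labeled molecules", {
  mixed <- unlist(lapply(1:40, function(s) {
    sim <- simulate_smlm(sim_config(true_density = 0.5, field = c(10, 10),
                                    label_model = "dual_color", n_frames = 2,
                                    seed = s))
    ch <- sim$truth$molecules$channels
    vapply(strsplit(ch, ","), function(v) length(unique(v)) == 2, logical(1))
  }))
  se <- sqrt(0.25 / length(mixed))
  expect_lt(abs(mean(mixed) - 0.5), 3 * se)
})

test_that("mean-squared displacement follows 4*D*dt*lag", {
  D <- 0.1; dt <- 0.032
  msd_by_lag <- matrix(0, 20, 5)
  for (s in 1:20) {
    sim <- simulate_smlm(sim_config(true_density = 0.4, field = c(20, 20),
                                    diffusion_coeff = D, bleach_prob = 0,
                                    detection_prob = 1, seed = s))
    tr <- sim$truth$trajectories
    for (lag in 1:5) {
      d <- tr[-(1:lag), , , drop = FALSE] -
        tr[1:(dim(tr)[1] - lag), , , drop = FALSE]
      msd_by_lag[s, lag] <- mean(d[, , 1]^2 + d[, , 2]^2)
    }
  }
  msd <- colMeans(msd_by_lag)
  fit <- lm(msd ~ 0 + I(1:5))
  expect_equal(unname(coef(fit)), 4 * D * dt, tolerance = 0.05)
})

test_that("per-frame localization counts decay as p_det * (1 - p_bleach)^frame", {
  tot <- numeric(150)
  n0 <- 0
  for (s in 1:10) {
    sim <- simulate_smlm(sim_config(true_density = 2, field = c(10, 10),
                                    bleach_prob = 0.03, detection_prob = 0.8,
                                    diffusion_coeff = 0, seed = s))
    tot <- tot + tabulate(sim$table$frame + 1L, 150)
    n0 <- n0 + sim$truth$n_mobile + sim$truth$n_immobile
  }
  expected <- 0.8 * n0 * (1 - 0.03)^(0:149)
  # compare the decay constant on the aggregated counts
  pos <- tot > 0
  slope <- coef(lm(log(tot[pos]) ~ I((0:149)[pos])))[2]
  expect_equal(unname(slope), log(1 - 0.03), tolerance = 0.05)
  expect_equal(tot[1], expected[1], tolerance = 0.1)
})

test_that("a fixed seed reproduces the simulation byte for byte", {
  cfg <- sim_config(true_density = 0.3, field = c(8, 8),
                    label_model = "dual_color", immobile_density = 0.1,
                    false_positive_rate = 0.01, seed = 77)
  expect_identical(simulate_smlm(cfg)$table, simulate_smlm(cfg)$table)
})

test_that("invalid config fields are rejected by name", {
  expect_error(sim_config(bleach_prob = 1.5), "bleach_prob")
  expect_error(sim_config(true_density = -1), "true_density")
  expect_error(sim_config(frame_interval = 0), "frame_interval")
  expect_error(sim_config(field = c(-1, 5)), "field")
})

test_that("channel misalignment is exact and identity is a no-op", {
  tab <- data.frame(frame = 0L, x_um = c(1, 2), y_um = c(3, 4),
                    channel = c("ch1", "ch2"))
  expect_equal(misalign_channels(tab), tab)
  mis <- misalign_channels(tab, shift = c(0.1, -0.05))
  expect_equal(mis$x_um, c(1, 2.1))
  expect_equal(mis$y_um, c(3, 3.95))
  expect_error(misalign_channels(tab, scale = 0), "non-invertible")
})

test_that("rendered movies put the brightest pixel at the molecule and conserve intensity", {
  tab <- data.frame(frame = 0:2, x_um = 2.31, y_um = 1.27)
  mv <- render_movie(tab, psf_sigma = 0.13, pixel_size = 0.1,
                     field = c(5, 5), photons = 1000, background = 0)
  for (f in 1:3) {
    idx <- which(mv[, , f] == max(mv[, , f]), arr.ind = TRUE)
    expect_equal(unname(idx[1, ]), c(13, 24))  # row = y, col = x (1-based)
    expect_equal(sum(mv[, , f]), 1000, tolerance = 0.01)
  }
  expect_error(render_movie(tab, pixel_size = 0), "pixel_size")
})

test_that("localization CSV round trip preserves the table", {
  sim <- simulate_smlm(sim_config(true_density = 0.2, field = c(5, 5),
                                  n_frames = 10, seed = 4))
  path <- withr::local_tempfile(fileext = ".csv")
  write_localizations(sim$table, path)
  back <- read_localizations(path)
  expect_equal(back$x_um, sim$table$x_um, tolerance = 1e-12)
  expect_equal(back$frame, sim$table$frame)
})
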