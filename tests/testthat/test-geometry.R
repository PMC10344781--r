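# Groove frame, antibody axis, docking angle and in-plane docking rotation

test_that("groove axis follows the helices and the origin sits at the groove", {
  cx <- template_complex("3m4e5-nyeso-a2")
  fr <- groove_frame(cx)
  expect_equal(abs(sum(fr$groove_axis * c(1, 0, 0))), 1, tolerance = 1e-6)
  expect_gt(sum(fr$groove_axis * c(1, 0, 0)), 0)  # peptide N->C orientation
  expect_gt(sum(fr$normal_axis * c(0, 0, 1)), 0.99)  # toward the antibody
  # axes orthonormal
  M <- rbind(fr$groove_axis, fr$normal_axis, fr$third_axis)
  expect_equal(M %*% t(M), diag(3), tolerance = 1e-8,
               ignore_attr = TRUE)
  pep_ca <- cx$atoms[cx$atoms$chain == "C" & cx$atoms$elety == "CA",
                     c("x", "y", "z")]
  expect_lt(sqrt(sum((colMeans(as.matrix(pep_ca)) - fr$origin)^2)), 10)
})

test_that("groove frame rotates covariantly under rigid motion", {
  cx <- template_complex("3m4e5-nyeso-a2")
  R <- rotation_matrix(c(2, -1, 1), 63)
  fr0 <- groove_frame(cx)
  fr1 <- groove_frame(transform_complex(cx, R, c(1, 2, 3)))
  expect_equal(fr1$groove_axis, as.numeric(R %*% fr0$groove_axis),
               tolerance = 1e-8)
  expect_equal(fr1$normal_axis, as.numeric(R %*% fr0$normal_axis),
               tolerance = 1e-8)
})

test_that("groove frame errors when helix residues are missing", {
  cx <- template_complex("3m4e5-nyeso-a2")
  broken <- cx
  drop <- broken$atoms$chain == "A" & broken$atoms$resno %in% 50:80
  broken$atoms <- broken$atoms[!drop, ]
  expect_error(groove_frame(broken), "missing")
})

test_that("antibody axis runs between the V-domain centroids", {
  cx <- template_complex("3m4e5-nyeso-a2")
  ax <- ab_axis(cx)
  alpha <- 50 * pi / 180
  expect_equal(ax$direction, c(cos(alpha), sin(alpha), 0), tolerance = 1e-9)
  # swapping heavy/light labels flips the axis sign only
  swapped <- cx
  swapped$roles[c("H", "L")] <- c("AB_LIGHT", "AB_HEAVY")
  ax2 <- ab_axis(swapped)
  expect_equal(ax2$direction, -ax$direction, tolerance = 1e-12)
  expect_equal(ax2$point, ax$point, tolerance = 1e-12)
})

test_that("docking angle reproduces constructed 0/90 degree cases and is rigid-invariant", {
  expect_equal(docking_angle(build_synthetic_complex("SIINFEKL", alpha_deg = 0)),
               0, tolerance = 1e-6)
  expect_equal(docking_angle(build_synthetic_complex("SIINFEKL", alpha_deg = 90)),
               90, tolerance = 1e-6)
  cx <- template_complex("ma2-mart1-a2")
  a0 <- docking_angle(cx)
  a1 <- docking_angle(transform_complex(cx, rotation_matrix(c(1, 1, 0), 120),
                                        c(-4, 7, 1)))
  expect_equal(a1, a0, tolerance = 1e-6)
})

test_that("docking rotation: identity, constructed +9, antisymmetry", {
  ref <- template_complex("3m4e5-nyeso-a2")
  expect_equal(as.numeric(docking_rotation(ref, ref)), 0, tolerance = 0.1)
  qry <- build_synthetic_complex("SLLMWITQV", alpha_deg = 50,
                                 rotation_deg = 9)
  expect_equal(as.numeric(docking_rotation(ref, qry)), 9, tolerance = 0.1)
  expect_equal(as.numeric(docking_rotation(ref, qry)),
               -as.numeric(docking_rotation(qry, ref)), tolerance = 0.1)
  # remains correct when the query is arbitrarily placed in space
  moved <- transform_complex(qry, rotation_matrix(c(3, 1, 2), 77), c(30, -10, 5))
  expect_equal(as.numeric(docking_rotation(ref, moved)), 9, tolerance = 0.1)
})

test_that("docking rotation refuses non-comparable scaffolds", {
  ref <- template_complex("3m4e5-nyeso-a2")
  noisy <- ref
  set.seed(9)
  hel <- noisy$atoms$chain == "A" & noisy$atoms$elety == "CA" &
    (noisy$atoms$resno %in% 50:86 | noisy$atoms$resno %in% 138:176)
  noisy$atoms$x[hel] <- noisy$atoms$x[hel] + rnorm(sum(hel), 0, 5)
  noisy$atoms$y[hel] <- noisy$atoms$y[hel] + rnorm(sum(hel), 0, 5)
  expect_error(docking_rotation(ref, noisy), "RMSD")
})

test_that("Kabsch superposition beats 1,000 random rigid placements", {
  set.seed(11)
  A <- matrix(rnorm(30), 10, 3)
  R <- rotation_matrix(c(1, -2, 0.5), 54)
  B <- A %*% t(R) + matrix(rnorm(30, 0, 0.1), 10, 3)
  B <- sweep(B, 2, c(3, -1, 2), "+")
  fit <- tcrmtools:::kabsch(A, B)
  rand_rmsd <- replicate(1000, {
    Rr <- rotation_matrix(rnorm(3), runif(1, 0, 360))
    Br <- sweep(B %*% t(Rr), 2, rnorm(3, 0, 2), "+")
    # best translation for this rotation: align centroids
    Br <- sweep(Br, 2, colMeans(Br) - colMeans(A), "-")
    sqrt(mean(rowSums((Br - A)^2)))
  })
  expect_lte(fit$rmsd, min(rand_rmsd))
})
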