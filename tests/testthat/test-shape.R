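test_that("PCA recovers uniform-spheroid axes and rotations", {
  set.seed(20)
  pts <- sample_in_spheroid(10000, c(1, 1, 4))
  p <- pca_axes(pts)
  expect_equal(sort(p$axis_lengths), c(1, 1, 4), tolerance = 0.05)
  expect_equal(p$center, c(0, 0, 0), tolerance = 0.05)
  # orientation rows orthonormal, det +1
  expect_lt(max(abs(p$orientation %*% t(p$orientation) - diag(3))), 1e-10)
  expect_equal(det(p$orientation), 1, tolerance = 1e-10)
  # equivariance: rotated cloud recovers the rotation up to sign/permutation
  rot <- random_rotation()
  p2 <- pca_axes(pts %*% t(rot))
  # principal (longest) axis of the rotated cloud = rot %*% old axis
  v1 <- p2$orientation[1, ]
  v0 <- as.numeric(rot %*% p$orientation[1, ])
  expect_equal(abs(sum(v1 * v0)), 1, tolerance = 1e-3)
  # degenerate input
  flat <- cbind(rnorm(100), rnorm(100), 0)
  expect_error(pca_axes(flat), "rank")
  expect_error(pca_axes(matrix(0, 3, 3)), "at least 4")
})

test_that("shape classification follows the axis-gap rule", {
  expect_equal(classify_shape(c(1, 1, 1)), "sphere")
  expect_equal(classify_shape(c(1, 1.05, 1.1)), "sphere")
  expect_equal(classify_shape(c(1, 1, 4)), "prolate")
  expect_equal(classify_shape(c(1, 4, 4)), "oblate")
  # tolerance sensitivity: same axes flip class as tol shrinks
  expect_equal(classify_shape(c(1, 1.02, 1.3), tol = 0.4), "sphere")
  expect_equal(classify_shape(c(1, 1.02, 1.3), tol = 0.15), "prolate")
  expect_equal(classify_shape(c(1, 1.28, 1.3), tol = 0.15), "oblate")
  expect_error(classify_shape(c(2, 1, 3)), "sorted")
})

test_that("fit_spheroid labels clean clouds and is rotation/scale invariant", {
  set.seed(21)
  pts <- sample_in_spheroid(4000, c(2, 2, 8))
  fit <- fit_spheroid(pts)
  expect_equal(fit$label, "prolate")
  expect_equal(fit$beta, 4, tolerance = 0.15)
  expect_lte(fit$phi, 1 + 1e-9)
  # Phi invariant under rigid rotation and uniform scaling
  rot <- random_rotation()
  fit_r <- fit_spheroid(pts %*% t(rot) * 3.7)
  expect_equal(fit_r$phi, fit$phi, tolerance = 1e-9)
  expect_equal(fit_r$label, fit$label)
  # surface refinement stays close to the moment fit on a clean cloud
  fit_s <- fit_spheroid(pts, method = "surface")
  expect_equal(fit_s$semi_axes, fit$semi_axes, tolerance = 0.1)
  # sphere: phi = 1 within tolerance and label sphere
  sp <- sample_in_spheroid(4000, c(3, 3, 3))
  fsp <- fit_spheroid(sp)
  expect_equal(fsp$label, "sphere")
  expect_gt(fsp$phi, 0.99)
})

test_that("rescale_profile interpolates without extrapolating", {
  prof <- data.frame(l = seq(0.1, 0.9, by = 0.1),
                     p_c = seq(0.9, 0.1, by = -0.1))
  # identity on its own grid
  same <- rescale_profile(prof, prof$l)
  expect_equal(same$p_c, prof$p_c, tolerance = 1e-12)
  # outside support -> NA, never extrapolated
  out <- rescale_profile(prof, c(0.05, 0.5, 0.95))
  expect_true(is.na(out$p_c[1]))
  expect_true(is.na(out$p_c[3]))
  expect_equal(out$p_c[2], 0.5, tolerance = 1e-12)
  # monotone input stays monotone under linear interpolation
  grid <- seq(0.12, 0.88, by = 0.02)
  mono <- rescale_profile(prof, grid)
  expect_true(all(diff(mono$p_c) <= 1e-12))
  expect_error(rescale_profile(prof, c(0, 0.5)), "grid")
  # subsampled chain agrees at shared nodes
  l2 <- prof$l[c(1, 3, 5, 7, 9)]
  sub <- rescale_profile(data.frame(l = l2, p_c = prof$p_c[c(1, 3, 5, 7, 9)]),
                         l2)
  expect_equal(sub$p_c, prof$p_c[c(1, 3, 5, 7, 9)], tolerance = 1e-12)
})

test_that("cross-chromosome normalization: symmetry and unit areas", {
  grid <- seq(0.1, 1, by = 0.1)
  curve <- data.frame(l = grid, p_c = grid^(-1.2))
  res <- normalize_across_chromosomes(list(a = curve, b = curve, c = curve))
  # identical curves: flat ratio 1 after step 1, area 1 after step 2
  flat <- res$normalized / res$normalized[1, 1]
  expect_equal(max(abs(flat - flat[1, 1])), 0, tolerance = 1e-9)
  areas <- apply(res$normalized, 2, function(y)
    sum(diff(grid) * (y[-1] + y[-length(y)]) / 2))
  expect_equal(unname(areas), rep(1, 3), tolerance = 1e-9)
})

test_that("cross-chromosome normalization matches a hand-computed table", {
  # two chromosomes, three nodes, worked by hand:
  # curves u = (4, 2, 1), v = (2, 2, 2) on l = (0.2, 0.5, 1.0)
  # mean curve m = (3, 2, 1.5); ratios u/m = (4/3, 1, 2/3), v/m = (2/3, 1, 4/3)
  # trapezoid areas: u: 0.3*(4/3+1)/2 + 0.5*(1+2/3)/2 = 0.35 + 0.41666... = 0.76666...
  #                  v: 0.3*(2/3+1)/2 + 0.5*(1+4/3)/2 = 0.25 + 0.58333... = 0.83333...
  grid <- c(0.2, 0.5, 1.0)
  u <- data.frame(l = grid, p_c = c(4, 2, 1))
  v <- data.frame(l = grid, p_c = c(2, 2, 2))
  res <- normalize_across_chromosomes(list(u = u, v = v))
  expect_equal(res$mean_curve, c(3, 2, 1.5))
  expect_equal(res$normalized[, "u"], c(4 / 3, 1, 2 / 3) / (23 / 30),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(res$normalized[, "v"], c(2 / 3, 1, 4 / 3) / (25 / 30),
               tolerance = 1e-12, ignore_attr = TRUE)
  # masked zero nodes warn
  w <- data.frame(l = grid, p_c = c(0, 1, 1))
  z <- data.frame(l = grid, p_c = c(0, 1, 1))
  expect_warning(normalize_across_chromosomes(list(w = w, z = z)), "masked")
})

test_that("shape_report summarizes labeled ensembles correctly", {
  set.seed(22)
  ens <- list(
    round_chr = lapply(1:6, function(i) sample_in_spheroid(500, c(2, 2, 2))),
    long_chr = lapply(1:6, function(i) sample_in_spheroid(500, c(1.5, 1.5, 6)))
  )
  rep1 <- shape_report(ens)
  rep2 <- shape_report(ens)
  expect_identical(rep1, rep2)  # deterministic given input order
  expect_equal(rep1$chromosome, c("long_chr", "round_chr"))  # sorted by phi
  r_round <- rep1[rep1$chromosome == "round_chr", ]
  expect_equal(r_round$frac_prolate, 0)
  expect_gt(r_round$mean_phi, 0.99)
  r_long <- rep1[rep1$chromosome == "long_chr", ]
  expect_gte(r_long$frac_prolate, 0.9)
  expect_lt(r_long$mean_phi, 0.9)
})
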