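test_that("axes_from_density recovers the requested density and volume", {
  g <- axes_from_density(150, 0.25, beta = 1)
  expect_equal(g$a, (450 / pi)^(1 / 3), tolerance = 1e-12)
  expect_equal(g$b, g$a)
  expect_equal(g$c, g$a)

  g4 <- axes_from_density(150, 0.25, beta = 4)
  expect_equal(g4$c / g4$a, 4, tolerance = 1e-12)
  expect_equal(4 / 3 * pi * g4$a * g4$b * g4$c, 600, tolerance = 1e-12)
  expect_equal(g4$a, 3.30, tolerance = 0.005)
  expect_equal(g4$c, 13.19, tolerance = 0.005)

  # equal volumes at equal (N, rho), any beta; density round trip to 1e-12
  for (beta in c(0.25, 0.5, 1, 2, 4)) {
    g <- axes_from_density(137, 0.15, beta)
    v <- 4 / 3 * pi * g$a * g$b * g$c
    expect_equal(v, 137 / 0.15, tolerance = 1e-12)
    expect_equal(137 / v, 0.15, tolerance = 1e-12)
  }
  expect_error(axes_from_density(-1, 0.25, 1), "positive")
  expect_error(axes_from_density(150, 0, 1), "positive")
})

test_that("spheroid inside test follows the level-set contract", {
  rot <- diag(3)[c(2, 3, 1), ]  # cyclic permutation, det +1
  g <- spheroid(2, 2, 8, center = c(1, -1, 0.5), orientation = rot)
  expect_true(inside_spheroid(g, g$center))
  # a point on the surface along a body axis
  p_surface <- g$center + as.numeric(t(rot) %*% c(0, 0, 8))
  expect_equal(level_set(g, p_surface), 1, tolerance = 1e-12)
  expect_false(inside_spheroid(g, p_surface * 1.5))
  expect_error(spheroid(1, 1, -1), "positive")
  expect_error(spheroid(1, orientation = matrix(1, 3, 3)), "orthonormal")
})

test_that("WCA energy and force match the closed form and vanish at cutoff", {
  ff <- force_field()
  rc <- 2^(1 / 6)
  expect_identical(wca_energy(rc, ff), 0)
  expect_identical(wca_force(rc, ff), 0)
  expect_equal(wca_energy(1, ff), 1)  # 4(1-1) + 1
  # direct arithmetic at r = 0.9
  r <- 0.9
  expect_equal(wca_energy(r, ff), 4 * ((1 / r)^12 - (1 / r)^6) + 1,
               tolerance = 1e-14)
  expect_error(wca_energy(0, ff), "singular")
  # C1 continuity at the cutoff
  expect_lt(abs(wca_energy(rc - 1e-8, ff) - wca_energy(rc + 1e-8, ff)), 1e-6)
  expect_lt(abs(wca_force(rc - 1e-8, ff) - wca_force(rc + 1e-8, ff)), 1e-5)
})

test_that("FENE energy diverges at R0 and combines with WCA to the 0.97 bond", {
  ff <- force_field()
  expect_equal(fene_energy(1e-12, ff), 0, tolerance = 1e-10)
  expect_error(fene_energy(1.5, ff), "overstretch")
  expect_error(fene_force(2, ff), "overstretch")
  # independent 1-D minimization of the bonded pair potential
  u <- function(r) fene_energy(r, ff) + wca_energy(r, ff)
  rmin <- optimize(u, c(0.5, 1.3))$minimum
  expect_equal(rmin, 0.97, tolerance = 0.01)
})

test_that("forces are negative gradients of energies (central differences)", {
  ff <- force_field()
  h <- 1e-6
  set.seed(1)
  r_wca <- runif(100, 0.75, 1.3)
  num <- -(wca_energy(r_wca + h, ff) - wca_energy(r_wca - h, ff)) / (2 * h)
  # relative error 1e-5 where the force is non-negligible
  sel <- abs(num) > 1e-8
  expect_lt(max(abs(num[sel] - wca_force(r_wca[sel], ff)) / abs(num[sel])),
            1e-5)
  r_fene <- runif(100, 0.05, 1.4)
  numf <- -(fene_energy(r_fene + h, ff) - fene_energy(r_fene - h, ff)) / (2 * h)
  expect_lt(max(abs(numf - fene_force(r_fene, ff)) / abs(numf)), 1e-5)
})

test_that("wall force is zero deep inside and repels inward near the wall", {
  g <- spheroid(6)
  ff <- force_field()
  shell <- fibonacci_shell(g, ff$wall_spacing)
  for (mode in c("shell_beads", "analytic")) {
    expect_equal(wall_force(c(0, 0, 0), g, ff, mode, shell = shell),
                 c(0, 0, 0))
    # exactly at the cutoff depth: zero force
    p0 <- c(6 - 2^(1 / 6) - 1e-9, 0, 0)
    expect_equal(wall_force(p0, g, ff, "analytic"), c(0, 0, 0))
    # closer: force along -x
    p1 <- c(6 - 0.6, 0, 0)
    f1 <- wall_force(p1, g, ff, mode, shell = shell)
    expect_lt(f1[1], 0)
  }
  # a bead found outside is still pushed inward
  fout <- wall_force(c(7, 0, 0), g, ff, "analytic")
  expect_lt(fout[1], 0)
})

test_that("shell-bead and analytic walls agree near the surface of a sphere", {
  g <- spheroid(6)
  ff <- force_field()
  shell <- fibonacci_shell(g, ff$wall_spacing)
  set.seed(7)
  u <- matrix(rnorm(300), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  pts <- u * (6 - 0.5)  # 0.5 sigma below the surface
  fs <- wall_force(pts, g, ff, "shell_beads", shell = shell)
  fa <- wall_force(pts, g, ff, "analytic")
  ms <- sqrt(rowSums(fs^2)); ma <- sqrt(rowSums(fa^2))
  # same direction (inward)
  cosang <- rowSums(fs * fa) / (ms * ma)
  expect_gt(min(cosang), 0.99)
  # magnitudes within 20%
  expect_lt(max(abs(ms / ma - 1)), 0.2)
})

test_that("surface area closed forms match quadrature; sphericity behaves", {
  skip_if_not_installed("pracma")
  sv_sphere <- spheroid_surface_volume(c(1, 1, 1))
  expect_equal(sv_sphere$surface_area, 4 * pi, tolerance = 1e-12)
  expect_equal(sv_sphere$volume, 4 * pi / 3, tolerance = 1e-12)
  expect_equal(sphericity(sv_sphere$volume, sv_sphere$surface_area), 1,
               tolerance = 1e-12)

  # prolate (1,1,2): exact closed form vs quadrature, Phi ~ 0.93
  sv <- spheroid_surface_volume(c(1, 1, 2))
  expect_equal(sv$surface_area, ellipsoid_surface_quadrature(c(1, 1, 2)),
               tolerance = 1e-3)
  phi <- sphericity(sv$volume, sv$surface_area)
  expect_equal(phi, 0.93, tolerance = 0.005)

  # oblate (1, 2, 2)
  sv_o <- spheroid_surface_volume(c(1, 2, 2))
  expect_equal(sv_o$surface_area, ellipsoid_surface_quadrature(c(2, 2, 1)),
               tolerance = 1e-3)

  # triaxial via Thomsen, within the 1.1% known bound of quadrature
  sv_t <- spheroid_surface_volume(c(1, 2, 3))
  quad <- ellipsoid_surface_quadrature(c(1, 2, 3))
  expect_lt(abs(sv_t$surface_area / quad - 1), 0.011)

  # isoperimetric inequality: Phi <= 1 for assorted spheroids
  set.seed(2)
  for (i in 1:20) {
    ax <- sort(runif(3, 0.5, 4))
    sv_i <- spheroid_surface_volume(ax)
    expect_lte(sphericity(sv_i$volume, sv_i$surface_area), 1 + 1e-9)
  }
  expect_error(sphericity(-1, 1), "positive")
})

test_that("fibonacci shell lies on the surface with bounded spacing", {
  g <- spheroid(3, 3, 6)
  sh <- fibonacci_shell(g, spacing = 0.7)
  expect_true(all(abs(level_set(g, sh) - 1) < 1e-9))
  # nearest-neighbour spacing below the requested bound
  set.seed(3)
  idx <- sample.int(nrow(sh), 200)
  nn <- vapply(idx, function(i) {
    d2 <- colSums((t(sh) - sh[i, ])^2)
    sqrt(sort(d2)[2])
  }, numeric(1))
  expect_lt(max(nn), 0.7)
})
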