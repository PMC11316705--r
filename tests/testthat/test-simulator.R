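test_that("chain initialization is confined, bonded and deterministic", {
  g <- axes_from_density(150, 0.25, 1)
  x <- initialize_chain(g, 150, seed = 1)
  expect_equal(dim(x), c(150L, 3L))
  expect_true(all(inside_spheroid(g, x)))
  b <- sqrt(rowSums((x[-1, ] - x[-150, ])^2))
  expect_equal(b, rep(0.97, 149), tolerance = 1e-12)
  expect_identical(x, initialize_chain(g, 150, seed = 1))
  expect_false(identical(x, initialize_chain(g, 150, seed = 2)))
  expect_error(initialize_chain(spheroid(1), 150), "too small")
})

test_that("push-off removes overlaps without overstretching bonds", {
  g <- axes_from_density(100, 0.25, 1)
  wall <- spheroid(g$a + 1, g$b + 1, g$c + 1)
  x <- initialize_chain(g, 100, seed = 3)
  expect_lt(min_pair_distance(x), 0.8)  # random walk self-intersects
  y <- push_off(x, wall, wall_mode = "shell_beads")
  expect_gte(min_pair_distance(y), 0.8)
  b <- sqrt(rowSums((y[-1, ] - y[-100, ])^2))
  expect_lt(max(b), 1.5)
  # no-op safety: already overlap-free input stays overlap-free
  z <- push_off(y, wall, wall_mode = "shell_beads")
  expect_gte(min_pair_distance(z), 0.8)
})

test_that("trajectories are deterministic in the seed", {
  cfg <- sim_config(30, 0.25, 1, n_steps_equil = 2000, n_steps_prod = 2000,
                    sample_every = 200, seed = 5)
  t1 <- run_simulation(cfg)
  t2 <- run_simulation(cfg)
  expect_identical(t1$frames, t2$frames)
  cfg2 <- sim_config(30, 0.25, 1, n_steps_equil = 2000, n_steps_prod = 2000,
                     sample_every = 200, seed = 6)
  expect_false(identical(run_simulation(cfg2)$frames, t1$frames))
})

test_that("confinement holds across densities and shapes", {
  for (case in list(c(0.05, 4), c(0.15, 0.25), c(0.25, 1))) {
    cfg <- sim_config(40, case[1], case[2], n_steps_equil = 5000,
                      n_steps_prod = 5000, sample_every = 250, seed = 8,
                      wall_mode = "shell_beads")
    traj <- run_simulation(cfg)
    # penetration tolerance: 0.1 sigma beyond the wall surface
    tolgeom <- spheroid(traj$geom$a + 0.1, traj$geom$b + 0.1,
                        traj$geom$c + 0.1)
    lev <- apply(traj$frames, 3, function(x) max(level_set(tolgeom, x)))
    expect_lte(max(lev), 1)
  }
})

test_that("thermostat holds the temperature and bonds stay in range", {
  traj <- short_confined_traj()
  expect_equal(traj$ekin_per_bead, 1.5, tolerance = 0.02)
  bonds <- apply(traj$frames, 3, function(x)
    sqrt(rowSums((x[-1, ] - x[-nrow(x), ])^2)))
  expect_gt(min(bonds), 0.8)
  expect_lt(max(bonds), 1.5)
  expect_equal(mean(bonds), 0.97, tolerance = 0.01)
})

test_that("symplectic limit: energy drift is small with the thermostat off", {
  # equilibrate with thermostat, then continue at gamma = 0
  g <- axes_from_density(40, 0.15, 1)
  cfg <- sim_config(40, 0.15, 1, n_steps_equil = 5000, n_steps_prod = 1,
                    sample_every = 1, seed = 9, wall_mode = "analytic")
  warm <- run_simulation(cfg)
  x0 <- warm$frames[, , 1]
  cfg0 <- sim_config(40, 0.15, 1, gamma = 0, dt = 0.005,
                     n_steps_equil = 0, n_steps_prod = 10000,
                     sample_every = 100, seed = 9, wall_mode = "analytic")
  nve <- run_simulation(cfg0, x0 = x0, record_energy = TRUE)
  e <- nve$energy
  drift <- abs(e[length(e)] - e[1]) / 40  # per bead over 1e4 steps
  expect_lt(drift, 1e-3)
  # semiflexible chain: bending forces must conserve energy too
  ffb <- force_field(k_bend = 2)
  cfgb <- sim_config(40, 0.15, 1, gamma = 0, dt = 0.003,
                     n_steps_equil = 0, n_steps_prod = 10000,
                     sample_every = 100, seed = 9, wall_mode = "analytic",
                     ff = ffb)
  nveb <- run_simulation(cfgb, x0 = x0, record_energy = TRUE)
  eb <- nveb$energy
  expect_lt(abs(eb[length(eb)] - eb[1]) / 40, 1e-3)
})

test_that("equilibration diagnostics flag drift and accept stationary series", {
  set.seed(10)
  white <- rnorm(200) + 5
  d <- equilibration_diagnostics(white)
  expect_lt(d$tau_int, 1.6)  # iid limit: ~1 frame
  expect_true(d$pass)
  drifting <- seq(1, 3, length.out = 200) + rnorm(200, sd = 0.05)
  expect_false(equilibration_diagnostics(drifting)$pass)
  expect_error(equilibration_diagnostics(rnorm(10)), "insufficient")
  # a production run at low density passes
  traj <- short_confined_traj()
  expect_true(equilibration_diagnostics(traj)$pass)
})
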