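options(testthat.progress.max_fails = 100L)

# Shared oracles and fixtures, independent of the implementation paths they
# check.

# Gaussian-chain contact probability: R^2(k) ~ (k b^2 / 3) * chisq_3, so
# P(|R| < rc) = pchisq(3 rc^2 / (k b^2), df = 3).
ideal_contact_prob <- function(k, rc, bond = 0.97) {
  pchisq(3 * rc^2 / (k * bond^2), df = 3)
}

# Uniform rejection sampler inside an axis-aligned spheroid.
sample_in_spheroid <- function(n, axes) {
  out <- matrix(NA_real_, 0, 3)
  while (nrow(out) < n) {
    m <- matrix(runif(3 * 2 * n, -1, 1), ncol = 3)
    keep <- rowSums(m^2) <= 1
    out <- rbind(out, sweep(m[keep, , drop = FALSE], 2, axes, "*"))
  }
  out[seq_len(n), , drop = FALSE]
}

# Random rotation matrix (QR of a Gaussian matrix, det +1).
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 3] <- -q[, 3]
  q
}

# Ellipsoid surface area by 2-D quadrature over spherical parameters.
ellipsoid_surface_quadrature <- function(axes) {
  a <- axes[1]; b <- axes[2]; c <- axes[3]
  # |dr/dtheta x dr/dphi| for r = (a st cp, b st sp, c ct)
  f <- function(theta, phi) {
    st <- sin(theta); ct <- cos(theta)
    sp <- sin(phi); cp <- cos(phi)
    ex <- b * c * st * cp
    ey <- a * c * st * sp
    ez <- a * b * ct
    st * sqrt(ex^2 + ey^2 + ez^2)
  }
  pracma::integral2(f, 0, pi, 0, 2 * pi, reltol = 1e-10)$Q
}

# A short confined trajectory cached across tests.
.fixture_env <- new.env(parent = emptyenv())

short_confined_traj <- function() {
  if (is.null(.fixture_env$traj)) {
    cfg <- sim_config(50, 0.25, 1, n_steps_equil = 20000,
                      n_steps_prod = 20000, sample_every = 100, seed = 42,
                      wall_mode = "shell_beads")
    .fixture_env$traj <- run_simulation(cfg)
  }
  .fixture_env$traj
}
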