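straight_chain <- function(n, bond = 0.97) {
  cbind(bond * (seq_len(n) - 1), 0, 0)
}

test_that("internal distances of a straight chain follow (k b)^2", {
  x <- straight_chain(20)
  prof <- mean_squared_internal_distance(x, last_fraction = 1)
  expect_equal(prof$r2_mean, (prof$k * 0.97)^2, tolerance = 1e-12)
  expect_equal(prof$l, prof$k / 20)
  expect_equal(prof$n_pairs, 20 - prof$k)
})

test_that("internal distances match a brute-force double loop", {
  set.seed(11)
  x <- matrix(rnorm(60), ncol = 3)
  prof <- mean_squared_internal_distance(x, last_fraction = 1)
  n <- nrow(x)
  brute <- sapply(seq_len(n - 1), function(k) {
    v <- sapply(seq_len(n - k), function(i) sum((x[i, ] - x[i + k, ])^2))
    mean(v)
  })
  expect_equal(prof$r2_mean, brute, tolerance = 1e-12)
})

test_that("ideal-chain ensemble reproduces <R^2(k)> = k b^2", {
  traj <- generate_free_chain("ideal", n_beads = 60, bond = 0.97,
                              n_samples = 400, seed = 12)
  prof <- mean_squared_internal_distance(traj, last_fraction = 1)
  for (k in c(1, 5, 10, 20)) {
    row <- prof[prof$k == k, ]
    se <- k * 0.97^2 * sqrt(2 / (3 * row$n_pairs))  # crude SE bound
    expect_lt(abs(row$r2_mean - k * 0.97^2), 3 * se + 0.02 * k)
  }
})

test_that("contact counting matches definition and brute force", {
  # straight chain with bond 0.97: k=2 gives 1.94 < 2 (contact), k>=3 none
  x <- straight_chain(30)
  pc <- contact_probability(x, last_fraction = 1)
  expect_equal(pc$p_c[pc$k == 2], 1)
  expect_true(all(pc$p_c[pc$k >= 3] == 0))
  # brute-force enumeration on a random 10-bead conformation
  set.seed(13)
  y <- matrix(rnorm(30, sd = 1.2), ncol = 3)
  pcy <- contact_probability(y, r_cutoff = 2, min_separation = 2,
                             last_fraction = 1)
  for (k in 2:9) {
    cnt <- sum(sapply(seq_len(10 - k), function(i)
      sqrt(sum((y[i, ] - y[i + k, ])^2)) < 2))
    expect_equal(pcy$contacts[pcy$k == k], cnt)
  }
  expect_true(all(pcy$p_c >= 0 & pcy$p_c <= 1))
  expect_true(all(pcy$contacts <= pcy$n_pairs))
  expect_equal(pcy$p_c, pcy$contacts / pcy$n_pairs)
})

test_that("cutoff inequality is strict", {
  x <- rbind(c(0, 0, 0), c(1.1, 0, 0), c(2, 0, 0))  # |1-3| = 2 exactly
  pc <- contact_probability(x, r_cutoff = 2, min_separation = 2,
                            last_fraction = 1)
  expect_equal(pc$contacts[pc$k == 2], 0)
})

test_that("contact and distance profiles enumerate identical pairs", {
  traj <- short_confined_traj()
  pc <- contact_probability(traj, min_separation = 1)
  r2 <- mean_squared_internal_distance(traj)
  expect_equal(pc$n_pairs, r2$n_pairs)
  expect_equal(pc$k, r2$k)
})

test_that("scaling fit is exact on power laws and flat profiles", {
  l <- seq(0.02, 0.5, by = 0.01)
  prof <- data.frame(l = l, p_c = l^(-1.5))
  fit <- fit_scaling_exponent(prof)
  expect_equal(fit$alpha, 1.5, tolerance = 1e-10)
  expect_lt(fit$stderr, 1e-10)
  expect_equal(predict(fit, 0.1), 0.1^(-1.5), tolerance = 1e-8)
  expect_equal(unname(coef(fit)["alpha"]), 1.5, tolerance = 1e-10)
  flat <- data.frame(l = l, p_c = rep(0.3, length(l)))
  expect_equal(fit_scaling_exponent(flat)$alpha, 0, tolerance = 1e-12)
  # log-binned fit is exact on a clean power law too
  binned <- fit_scaling_exponent(prof, log_bins = 6)
  expect_equal(binned$alpha, 1.5, tolerance = 1e-10)
  expect_equal(binned$n_points, 6)
  expect_error(fit_scaling_exponent(data.frame(l = c(0.1, 0.15),
                                               p_c = c(1, 1))),
               "insufficient")
})

test_that("scaling fit recovers a noisy exponent within its stderr", {
  set.seed(14)
  ok <- 0
  for (rep in 1:10) {
    l <- exp(seq(log(0.07) + 0.01, log(0.2) - 0.01, length.out = 50))
    prof <- data.frame(l = l, p_c = 2 * l^(-2.18) *
                         exp(rnorm(50, sd = 0.05)))
    fit <- fit_scaling_exponent(prof, 0.07, 0.2)
    if (abs(fit$alpha - 2.18) < 3 * fit$stderr) ok <- ok + 1
  }
  expect_gte(ok, 9)
})

test_that("replica pooling averages counts and reports seed CIs", {
  set.seed(15)
  profs <- lapply(1:5, function(s) {
    x <- matrix(rnorm(90, sd = 1.5), ncol = 3)
    contact_probability(x, last_fraction = 1)
  })
  pooled <- pool_profiles(profs)
  expect_equal(pooled$contacts,
               Reduce(`+`, lapply(profs, `[[`, "contacts")))
  expect_equal(pooled$p_c, pooled$contacts / pooled$n_pairs)
})

test_that("normalized distance distribution has unit area and unit mean x^2", {
  traj <- short_confined_traj()
  dd <- distance_distribution(traj, k = 10, n_bins = 30)
  expect_equal(sum(dd$density * diff(dd$breaks)), 1, tolerance = 1e-9)
  expect_equal(mean(dd$x^2), 1, tolerance = 1e-12)
  expect_error(distance_distribution(traj, k = 500), "k must be")
  # degenerate case: all distances equal -> all mass at x = 1
  x <- straight_chain(12, bond = 1)
  dd1 <- distance_distribution(x, k = 3, n_bins = 10, last_fraction = 1)
  expect_equal(sum(dd1$density > 0), 1)
  occupied <- dd1$mids[dd1$density > 0]
  expect_equal(occupied, 1, tolerance = 0.1)
})

test_that("ideal-chain distance distribution matches the Gaussian radial law", {
  traj <- generate_free_chain("ideal", n_beads = 40, bond = 1,
                              n_samples = 800, seed = 16)
  dd <- distance_distribution(traj, k = 20, n_bins = 25, last_fraction = 1)
  # radial density of |r| for r ~ N(0, (k b^2 / 3) I), normalized by sqrt(<R^2>):
  # P(x) = sqrt(54/pi) x^2 exp(-3 x^2 / 2)
  expect_equal(mean(dd$x^2), 1, tolerance = 1e-12)
  theo <- sqrt(54 / pi) * dd$mids^2 * exp(-1.5 * dd$mids^2)
  expect_lt(max(abs(dd$density - theo)), 0.12)  # binning + sampling error
})
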