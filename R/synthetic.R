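#' Synthetic confined-chain ensembles with known ground-truth shape
#'
#' Desk-scale stand-in for an ensemble of per-chromosome 3D structure
#' replicas (as produced by Hi-C-based structure modelling): for each
#' "chromosome" and replica, a short confined Kremer-Grest simulation inside
#' a spheroid of the requested aspect ratio, keeping the final conformation.
#' Ground-truth geometry and the full parameterization are recorded in the
#' result, so an ensemble can be regenerated bit-identically from its
#' metadata.
#'
#' @param n_chrom Number of chromosomes.
#' @param n_beads Beads per chromosome (scalar or vector of length
#'   `n_chrom`).
#' @param beta Aspect ratio per chromosome (scalar or vector).
#' @param rho_sigma3 Reduced monomer density.
#' @param n_replicas Replicas per chromosome.
#' @param seed Master seed; per-replica seeds are derived deterministically.
#' @param n_steps Langevin steps per replica (after push-off).
#' @param wall_mode Wall mode (see [sim_config]).
#' @return Object of class `"ct_ensemble"`: `structures` (list per
#'   chromosome of replica coordinate matrices), `truth` (data frame of
#'   requested parameters and geometries) and `meta` (all arguments).
#' @export
generate_confined_ensemble <- function(n_chrom = 2, n_beads = 150, beta = 1,
                                       rho_sigma3 = 0.25, n_replicas = 10,
                                       seed = 1L, n_steps = 4000L,
                                       wall_mode = "shell_beads") {
  stopifnot(n_chrom >= 1, n_replicas >= 1, all(n_beads >= 2),
            all(beta > 0), rho_sigma3 > 0)
  n_beads <- rep_len(as.integer(n_beads), n_chrom)
  beta <- rep_len(beta, n_chrom)
  seed <- as.integer(seed)
  structures <- vector("list", n_chrom)
  names(structures) <- paste0("chr", seq_len(n_chrom))
  truth <- vector("list", n_chrom)
  for (ch in seq_len(n_chrom)) {
    geom <- axes_from_density(n_beads[ch], rho_sigma3, beta[ch])
    reps <- vector("list", n_replicas)
    for (r in seq_len(n_replicas)) {
      rseed <- (seed + 7919L * (ch - 1L) + 131L * r) %% .Machine$integer.max
      cfg <- sim_config(n_beads = n_beads[ch], rho_sigma3 = rho_sigma3,
                        beta = beta[ch], n_steps_equil = as.integer(n_steps),
                        n_steps_prod = 1L, sample_every = 1L, seed = rseed,
                        wall_mode = wall_mode, init = "random_walk")
      traj <- run_simulation(cfg, geom = geom)
      reps[[r]] <- traj$frames[, , n_frames(traj)]
    }
    structures[[ch]] <- reps
    truth[[ch]] <- data.frame(chromosome = names(structures)[ch],
                              n_beads = n_beads[ch], beta = beta[ch],
                              rho_sigma3 = rho_sigma3,
                              a = geom$a, b = geom$b, c = geom$c)
  }
  structure(list(structures = structures, truth = do.call(rbind, truth),
                 meta = list(n_chrom = n_chrom, n_beads = n_beads,
                             beta = beta, rho_sigma3 = rho_sigma3,
                             n_replicas = n_replicas, seed = seed,
                             n_steps = n_steps, wall_mode = wall_mode)),
            class = "ct_ensemble")
}

#' @export
print.ct_ensemble <- function(x, ...) {
  cat(sprintf("ct_ensemble: %d chromosome(s) x %d replica(s), seed=%d\n",
              x$meta$n_chrom, x$meta$n_replicas, x$meta$seed))
  print(x$truth, row.names = FALSE)
  invisible(x)
}

#' Free-chain reference ensembles
#'
#' `kind = "ideal"`: independent fixed-bond random walks (no excluded
#' volume), the analytic reference for Gaussian-chain observables
#' (`<R^2(k)> = k b^2`, contact probability from the chi-square radial law).
#' `kind = "saw"`: an unconfined Langevin run of the full Kremer-Grest chain
#' (WCA excluded volume, no wall), the self-avoiding-walk reference whose
#' contact decay approaches `l^(-2.18)` asymptotically.
#'
#' @param kind `"ideal"` or `"saw"`.
#' @param n_beads Chain length.
#' @param bond Bond length (sigma), used for `"ideal"`.
#' @param n_samples For `"ideal"`, the number of independent walks; for
#'   `"saw"`, the number of production frames kept.
#' @param seed Integer seed.
#' @param n_steps_equil,n_steps_prod Langevin lengths for `"saw"`.
#' @return A `"trajectory"` whose frames are the ensemble members
#'   (independent walks for `"ideal"`); metadata in `config`.
#' @export
generate_free_chain <- function(kind = c("ideal", "saw"), n_beads = 150,
                                bond = 0.97, n_samples = 200, seed = 1L,
                                n_steps_equil = 100 * n_beads^2,
                                n_steps_prod = n_steps_equil) {
  kind <- match.arg(kind)
  if (n_beads < 2) stop("n_beads must be at least 2", call. = FALSE)
  if (kind == "ideal") {
    old <- .Random.seed_store(); on.exit(.Random.seed_restore(old))
    set.seed(as.integer(seed))
    frames <- array(NA_real_, c(n_beads, 3, n_samples))
    for (s in seq_len(n_samples)) {
      u <- matrix(stats::rnorm(3 * (n_beads - 1)), ncol = 3)
      u <- bond * u / sqrt(rowSums(u^2))
      frames[, , s] <- rbind(0, apply(u, 2, cumsum))
    }
    cfg <- sim_config(n_beads = n_beads, rho_sigma3 = 1e-6,
                      n_steps_equil = 0L, n_steps_prod = n_samples,
                      sample_every = 1L, seed = as.integer(seed))
    structure(list(frames = frames, step_index = seq_len(n_samples),
                   config = cfg, geom = NULL, ekin_per_bead = NA_real_,
                   kind = "ideal", bond = bond),
              class = "trajectory")
  } else {
    traj <- run_free_chain(n_beads = n_beads, seed = seed,
                           n_steps_equil = n_steps_equil,
                           n_steps_prod = n_steps_prod,
                           sample_every = max(1L, as.integer(
                             n_steps_prod / n_samples)))
    traj$kind <- "saw"
    traj
  }
}

#' Toy power-law contact-profile sets
#'
#' Power-law curves `p_c(l) = A l^(-exponent)` with optional multiplicative
#' lognormal noise and a per-chromosome large-`l` plateau, for exercising the
#' fitting and normalization machinery against known ground truth.
#'
#' @param n_chrom Number of chromosomes.
#' @param grid Shared `l` grid in (0, 1].
#' @param exponents Ground-truth exponents (recycled to `n_chrom`).
#' @param noise Standard deviation of `log` multiplicative noise (0 = exact).
#' @param plateau Plateau level as a fraction of the curve value at the grid
#'   midpoint (0 disables).
#' @param seed Integer seed.
#' @return List of data frames (columns `l`, `p_c`) named `chr1..`, with the
#'   generating parameters in `attr(, "meta")`.
#' @export
generate_toy_profiles <- function(n_chrom = 3,
                                  grid = seq(0.02, 1, by = 0.02),
                                  exponents = 1.5, noise = 0, plateau = 0,
                                  seed = 1L) {
  stopifnot(n_chrom >= 1, all(exponents > 0), noise >= 0)
  if (any(grid <= 0) || any(grid > 1)) stop("grid must lie in (0, 1]",
                                            call. = FALSE)
  exponents <- rep_len(exponents, n_chrom)
  old <- .Random.seed_store(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  out <- lapply(seq_len(n_chrom), function(ch) {
    y <- grid^(-exponents[ch])
    if (plateau > 0) {
      lev <- plateau * y[which.min(abs(grid - stats::median(grid)))]
      y <- pmax(y, lev)
    }
    if (noise > 0) y <- y * exp(stats::rnorm(length(grid), 0, noise))
    p <- data.frame(l = grid, p_c = y)
    class(p) <- c("contact_profile", "data.frame")
    p
  })
  names(out) <- paste0("chr", seq_len(n_chrom))
  attr(out, "meta") <- list(n_chrom = n_chrom, exponents = exponents,
                            noise = noise, plateau = plateau, seed = seed,
                            grid = grid)
  out
}
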