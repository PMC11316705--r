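#' Simulation configuration
#'
#' Validated parameter set for one confined-chain Langevin run. Defaults are
#' the canonical choices for the Kremer-Grest chain at `kT = 1`:
#' velocity-Verlet/BAOAB with `dt = 0.01 tau`, friction `gamma = 1 / tau`.
#' The default equilibration length is `200 * n_beads^2` steps (several Rouse
#' times of the free chain) with an equally long production phase; analyses
#' at desk scale typically pass much shorter explicit lengths (see the
#' package vignette for the sizes used there).
#'
#' @param n_beads Chain length N.
#' @param rho_sigma3 Reduced monomer density `N / V` (sigma^-3).
#' @param beta Confinement aspect ratio `c / a`.
#' @param dt Integrator timestep (tau).
#' @param gamma Langevin friction (1/tau); 0 gives plain velocity Verlet.
#' @param kT Thermal energy (eps).
#' @param n_steps_equil,n_steps_prod Equilibration / production step counts.
#' @param sample_every Steps between saved production frames.
#' @param seed Integer seed; fully determines the trajectory.
#' @param wall_mode `"shell_beads"` (confinement shell built from repulsive
#'   surface monomers) or `"analytic"` (integrated sheet force; faster).
#' @param init Chain preparation. `"compressed_saw"` (default): a swollen
#'   self-avoiding coil is grown without confinement and then compressed
#'   into the target cavity by a slowly shrinking wall; `"compact"`: an
#'   ordered serpentine-packed blob (see [compact_chain]), the
#'   mitotic-like decondensation start used in chromosome-territory
#'   modelling; `"random_walk"`: a dense random-walk start inside the
#'   cavity followed by push-off (reaches local equilibrium fastest, but
#'   carries no large-scale territorial order).
#' @param n_steps_prep Unconfined swelling steps for `"compressed_saw"`.
#' @param n_steps_compress Wall-shrinking steps for `"compressed_saw"`.
#' @param ff A [force_field].
#' @return Object of class `"sim_config"`.
#' @export
sim_config <- function(n_beads = 150, rho_sigma3 = 0.25, beta = 1,
                       dt = 0.01, gamma = 1, kT = 1,
                       n_steps_equil = 200 * n_beads^2,
                       n_steps_prod = n_steps_equil,
                       sample_every = max(1L, as.integer(n_steps_prod / 500)),
                       seed = 1L,
                       wall_mode = c("shell_beads", "analytic"),
                       init = c("compressed_saw", "compact", "random_walk"),
                       n_steps_prep = 2 * n_beads^2,
                       n_steps_compress = 4 * n_beads^2,
                       ff = force_field()) {
  wall_mode <- match.arg(wall_mode)
  init <- match.arg(init)
  if (!is.finite(dt) || dt <= 0) stop("dt must be positive", call. = FALSE)
  if (!is.finite(rho_sigma3) || rho_sigma3 <= 0)
    stop("rho_sigma3 must be positive", call. = FALSE)
  if (!is.finite(beta) || beta <= 0) stop("beta must be positive", call. = FALSE)
  if (n_beads < 2) stop("n_beads must be at least 2", call. = FALSE)
  if (gamma < 0 || kT <= 0) stop("gamma >= 0 and kT > 0 required", call. = FALSE)
  if (n_steps_prod < sample_every)
    stop("n_steps_prod must be at least sample_every", call. = FALSE)
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be an integer", call. = FALSE)
  structure(list(n_beads = as.integer(n_beads), rho_sigma3 = rho_sigma3,
                 beta = beta, dt = dt, gamma = gamma, kT = kT,
                 n_steps_equil = as.integer(n_steps_equil),
                 n_steps_prod = as.integer(n_steps_prod),
                 sample_every = as.integer(sample_every), seed = seed,
                 wall_mode = wall_mode, init = init,
                 n_steps_prep = as.integer(n_steps_prep),
                 n_steps_compress = as.integer(n_steps_compress), ff = ff),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "sim_config: N=%d, rho*sigma^3=%g, beta=%g, dt=%g, gamma=%g, kT=%g\n  equil=%d, prod=%d, sample_every=%d, seed=%d, wall=%s\n",
    x$n_beads, x$rho_sigma3, x$beta, x$dt, x$gamma, x$kT,
    x$n_steps_equil, x$n_steps_prod, x$sample_every, x$seed, x$wall_mode))
  invisible(x)
}

ff_as_list <- function(ff) {
  list(k_fene = ff$k_fene, R0 = ff$R0, eps_wca = ff$eps_wca,
       sigma = ff$sigma, wall_eps = ff$wall_eps,
       wall_spacing = ff$wall_spacing,
       k_bend = if (is.null(ff$k_bend)) 0 else ff$k_bend)
}

#' Random-walk chain initialization inside a spheroid
#'
#' Grows a fixed-bond (default 0.97 sigma) random walk, re-drawing any step
#' that would leave the confinement; self-intersections are allowed (they are
#' removed later by [push_off]). Deterministic given `seed`.
#'
#' @param geom A [spheroid]; must be axis-aligned and centered (as produced
#'   by [axes_from_density]).
#' @param n_beads Number of beads.
#' @param seed Integer seed.
#' @param bond Bond length (sigma).
#' @param margin Keep beads at least this far inside the surface (sigma).
#' @param max_retries Re-draws allowed per step before restarting the walk.
#' @return An `n_beads` x 3 matrix of positions.
#' @export
initialize_chain <- function(geom, n_beads, seed = 1L, bond = 0.97,
                             margin = 0.5, max_retries = 200L) {
  stopifnot(inherits(geom, "spheroid"))
  if (min(geom$a, geom$b, geom$c) <= margin + bond)
    stop("geometry too small for chain initialization", call. = FALSE)
  inner <- spheroid(geom$a - margin, geom$b - margin, geom$c - margin,
                    center = geom$center, orientation = geom$orientation)
  old <- .Random.seed_store()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  for (attempt in 1:20) {
    x <- matrix(NA_real_, n_beads, 3)
    # start near the center
    repeat {
      p <- geom$center + stats::runif(3, -1, 1) * 0.25 *
        c(geom$a, geom$b, geom$c)
      if (level_set(inner, p) <= 1) break
    }
    x[1, ] <- p
    ok <- TRUE
    for (i in seq_len(n_beads - 1)) {
      placed <- FALSE
      for (r in seq_len(max_retries)) {
        u <- stats::rnorm(3)
        step <- bond * u / sqrt(sum(u^2))
        cand <- x[i, ] + step
        if (level_set(inner, cand) <= 1) {
          x[i + 1, ] <- cand
          placed <- TRUE
          break
        }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(x)
  }
  stop("geometry too small: failed to place the chain after bounded retries",
       call. = FALSE)
}

.Random.seed_store <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Compact serpentine chain initialization
#'
#' Lays the chain along a space-filling boustrophedon path over a cubic
#' lattice (spacing `h`), shaped to the confinement's aspect ratio and
#' centered in the cavity: a compact, ordered, locally dense conformation
#' emulating the mitotic-like state from which an interphase territory
#' decondenses. All bonds have length `h` and there are no overlaps, so the
#' conformation can be integrated immediately.
#'
#' @param geom A [spheroid] (the target cavity).
#' @param n_beads Number of beads.
#' @param h Lattice spacing (sigma); must lie in (sigma, R0).
#' @return An `n_beads` x 3 position matrix.
#' @export
compact_chain <- function(geom, n_beads, h = 1.1) {
  ax <- c(geom$a, geom$b, geom$c)
  # lattice dims proportional to the axes, smallest product >= n_beads
  lam <- (n_beads / prod(ax))^(1 / 3)
  dims <- pmax(1, round(lam * ax))
  while (prod(dims) < n_beads) {
    # grow the dimension with the most headroom relative to its axis
    room <- ax / (dims * h)
    i <- which.max(room)
    dims[i] <- dims[i] + 1
  }
  if (any(dims * h / 2 > 0.9 * ax))
    stop("cavity too flat/narrow for a compact initialization at this h",
         call. = FALSE)
  pts <- matrix(NA_real_, n_beads, 3)
  n <- 0L
  for (iz in seq_len(dims[3])) {
    ys <- if (iz %% 2 == 1) seq_len(dims[2]) else rev(seq_len(dims[2]))
    for (iy in ys) {
      fwd <- ((iy + iz) %% 2 == 0)
      xs <- if (fwd) seq_len(dims[1]) else rev(seq_len(dims[1]))
      for (ix in xs) {
        n <- n + 1L
        if (n > n_beads) break
        pts[n, ] <- c(ix, iy, iz)
      }
      if (n > n_beads) break
    }
    if (n > n_beads) break
  }
  pts <- sweep(pts, 2, colMeans(pts[seq_len(min(n_beads, nrow(pts))), ]))
  sweep(pts * h, 2, geom$center, "+")
}

#' Effective exclusion thickness of the repulsive wall
#'
#' The WCA wall is soft: beads are repelled over a layer of roughly one
#' monomer diameter, so a shell placed exactly on the target cavity surface
#' would shrink the accessible volume and raise the realized density above
#' `N / V`. The simulator therefore places the shell outward of the target
#' cavity by the Gibbs dividing surface of the planar wall potential,
#' `delta = integral_0^rc (1 - exp(-Phi(z) / kT)) dz`, where `Phi` is the
#' laterally integrated WCA sheet potential at the shell's bead density.
#' With default parameters `delta ~ 1.05 sigma`.
#'
#' @param ff A [force_field].
#' @param kT Thermal energy (eps).
#' @return Offset in sigma.
#' @export
wall_offset <- function(ff = force_field(), kT = 1) {
  rc <- 2^(1 / 6) * ff$sigma
  n_area <- 1 / ff$wall_spacing^2
  Iint <- function(r) {
    s6 <- (ff$sigma / r)^6
    4 * ff$wall_eps * (-s6^2 * r^2 / 10 + s6 * r^2 / 4) +
      ff$wall_eps * r^2 / 2
  }
  phi <- function(z) 2 * pi * n_area * (Iint(rc) - Iint(z))
  stats::integrate(function(z) 1 - exp(-pmin(phi(z) / kT, 700)), 0, rc)$value
}

.inflate <- function(geom, delta) {
  spheroid(geom$a + delta, geom$b + delta, geom$c + delta,
           center = geom$center, orientation = geom$orientation)
}

.wall_mode_int <- function(mode) {
  switch(mode, none = 0L, analytic = 1L, shell_beads = 2L,
         stop("unknown wall mode: ", mode, call. = FALSE))
}

.shell_for <- function(geom, ff, mode) {
  if (mode == "shell_beads") fibonacci_shell(geom, ff$wall_spacing)
  else matrix(0, 0, 3)
}

#' Soft push-off to remove overlaps
#'
#' Overdamped relaxation with the WCA pair force capped at a ramp of
#' increasing strength, ending at effectively full excluded volume. Removes
#' the self-intersections of a fresh random-walk initialization while keeping
#' every bond below `R0` and every bead inside the confinement.
#'
#' @param conf N x 3 position matrix (possibly overlapping).
#' @param geom A [spheroid], or `NULL` for an unconfined chain.
#' @param ff A [force_field].
#' @param n_steps Relaxation steps.
#' @param fcap_range Force-cap ramp (start, end), eps/sigma.
#' @param max_disp Per-step displacement clamp (sigma).
#' @param wall_mode Wall mode (see [sim_config]); ignored when `geom` is NULL.
#' @return Relaxed N x 3 position matrix. If overlaps below `0.8 sigma`
#'   remain, a warning reports the worst remaining pair distance.
#' @export
push_off <- function(conf, geom = NULL, ff = force_field(), n_steps = 2000L,
                     fcap_range = c(5, 2e4), max_disp = 0.02,
                     wall_mode = "shell_beads") {
  mode <- if (is.null(geom)) "none" else wall_mode
  axes <- if (is.null(geom)) numeric(0) else c(geom$a, geom$b, geom$c)
  shell <- if (is.null(geom)) matrix(0, 0, 3) else .shell_for(geom, ff, mode)
  out <- pushoff_cpp(conf, axes, .wall_mode_int(mode), shell, ff_as_list(ff),
                     as.integer(n_steps), fcap_range[1], fcap_range[2],
                     max_disp)
  dmin <- min_pair_distance(out)
  if (dmin < 0.8 * ff$sigma)
    warning(sprintf("push-off left overlaps: worst pair distance %.3f sigma",
                    dmin))
  out
}

#' Minimum nonbonded-or-bonded pair distance of a conformation
#' @param x N x 3 position matrix.
#' @return The smallest pairwise distance.
#' @export
min_pair_distance <- function(x) {
  min(stats::dist(x))
}

#' Run a confined-chain Langevin simulation
#'
#' Initializes a random-walk chain inside the spheroid implied by the
#' configuration (see [axes_from_density]), removes overlaps with [push_off],
#' then integrates Langevin dynamics (BAOAB splitting) for
#' `n_steps_equil + n_steps_prod` steps, recording every `sample_every`-th
#' production frame. The trajectory is fully determined by `config$seed`.
#'
#' @param config A [sim_config].
#' @param geom Optional [spheroid] overriding the density-derived one.
#' @param x0 Optional N x 3 starting conformation (skips initialization and
#'   push-off).
#' @param record_energy Record total energy at each saved frame.
#' @return Object of class `"trajectory"`: fields `frames` (N x 3 x n_frames
#'   array, sigma units), `step_index`, `config`, `geom`, `ekin_per_bead`,
#'   and optionally `energy`.
#' @export
run_simulation <- function(config, geom = NULL, x0 = NULL,
                           record_energy = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(geom))
    geom <- axes_from_density(config$n_beads, config$rho_sigma3, config$beta)
  ff <- config$ff
  # the wall shell sits outward of the target cavity by its exclusion
  # thickness, so the accessible volume realizes the nominal density
  wall <- .inflate(geom, wall_offset(ff, config$kT))
  axes_start <- numeric(0)
  n_compress <- 0L
  if (is.null(x0)) {
    if (config$init == "compact") {
      x0 <- compact_chain(geom, config$n_beads)
    } else if (config$init == "compressed_saw") {
      saw <- run_free_chain(config$n_beads, seed = config$seed,
                            dt = config$dt, gamma = config$gamma,
                            kT = config$kT,
                            n_steps_equil = config$n_steps_prep,
                            n_steps_prod = 1L, sample_every = 1L, ff = ff)
      x0 <- saw$frames[, , 1]
      x0 <- sweep(x0, 2, colMeans(x0))
      tgt <- c(wall$a, wall$b, wall$c)
      # start with the wall clear of every bead by >= 2 sigma
      s0 <- sqrt(max(rowSums(sweep(x0, 2, tgt, "/")^2)))
      axes_start <- tgt * max(s0, 1) + 2
      n_compress <- config$n_steps_compress
    } else {
      x0 <- initialize_chain(geom, config$n_beads, seed = config$seed)
      x0 <- suppressWarnings(
        push_off(x0, wall, ff, wall_mode = config$wall_mode))
    }
  }
  shell <- .shell_for(wall, ff, config$wall_mode)
  res <- md_run_cpp(x0, c(wall$a, wall$b, wall$c),
                    .wall_mode_int(config$wall_mode), shell, ff_as_list(ff),
                    config$dt, config$gamma, config$kT,
                    config$n_steps_equil, config$n_steps_prod,
                    config$sample_every, config$seed + 1L, record_energy,
                    axes_start, n_compress)
  structure(list(frames = res$frames, step_index = res$step_index,
                 config = config, geom = wall, cavity = geom,
                 ekin_per_bead = res$ekin_per_bead,
                 energy = if (record_energy) res$energy else NULL),
            class = "trajectory")
}

#' Run an unconfined chain (no wall)
#'
#' Same integrator as [run_simulation] but without any confinement; used for
#' the self-avoiding-walk reference ensemble.
#'
#' @inheritParams run_simulation
#' @param n_beads,seed,dt,gamma,kT,n_steps_equil,n_steps_prod,sample_every
#'   As in [sim_config].
#' @param ff A [force_field].
#' @return A `"trajectory"` (with `geom = NULL`).
#' @export
run_free_chain <- function(n_beads = 150, seed = 1L, dt = 0.01, gamma = 1,
                           kT = 1, n_steps_equil = 200 * n_beads^2,
                           n_steps_prod = n_steps_equil,
                           sample_every = max(1L, as.integer(n_steps_prod / 500)),
                           ff = force_field(), x0 = NULL,
                           record_energy = FALSE) {
  if (is.null(x0)) {
    # unconfined random walk + push-off
    old <- .Random.seed_store(); on.exit(.Random.seed_restore(old))
    set.seed(as.integer(seed))
    u <- matrix(stats::rnorm(3 * (n_beads - 1)), ncol = 3)
    u <- 0.97 * u / sqrt(rowSums(u^2))
    x0 <- rbind(0, apply(u, 2, cumsum))
    x0 <- suppressWarnings(push_off(x0, NULL, ff))
  }
  res <- md_run_cpp(x0, numeric(0), 0L, matrix(0, 0, 3), ff_as_list(ff),
                    dt, gamma, kT, as.integer(n_steps_equil),
                    as.integer(n_steps_prod), as.integer(sample_every),
                    as.integer(seed) + 1L, record_energy, numeric(0), 0L)
  cfg <- sim_config(n_beads = n_beads, rho_sigma3 = 1e-6, beta = 1, dt = dt,
                    gamma = gamma, kT = kT, n_steps_equil = n_steps_equil,
                    n_steps_prod = n_steps_prod, sample_every = sample_every,
                    seed = seed)
  structure(list(frames = res$frames, step_index = res$step_index,
                 config = cfg, geom = NULL,
                 ekin_per_bead = res$ekin_per_bead,
                 energy = if (record_energy) res$energy else NULL),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("trajectory: N=%d beads, %d frames (every %d steps), seed=%d\n",
              d[1], d[3], x$config$sample_every, x$config$seed))
  if (!is.null(x$geom))
    cat(sprintf("  confinement: a=%.3g b=%.3g c=%.3g sigma (beta=%.3g)\n",
                x$geom$a, x$geom$b, x$geom$c, x$geom$c / x$geom$a))
  invisible(x)
}

#' Number of frames / beads in a trajectory
#' @param traj A `"trajectory"`.
#' @return Integer count.
#' @export
n_frames <- function(traj) dim(traj$frames)[3]

#' @rdname n_frames
#' @export
n_beads <- function(traj) dim(traj$frames)[1]

#' Radius of gyration per frame
#' @param traj A `"trajectory"`.
#' @return Numeric vector, one Rg (sigma) per frame.
#' @export
radius_of_gyration <- function(traj) {
  apply(traj$frames, 3, function(x) {
    xc <- sweep(x, 2, colMeans(x))
    sqrt(mean(rowSums(xc^2)))
  })
}

#' Equilibration diagnostics for a trajectory
#'
#' Computes the radius-of-gyration time series, its integrated
#' autocorrelation time (sum of the empirical autocorrelation up to the first
#' non-positive lag), and a stationarity flag: the run passes when the 95%
#' confidence intervals of the first-half and second-half mean Rg overlap
#' (intervals use an effective sample size `n / (2 tau_int)`).
#'
#' @param traj A `"trajectory"`, or a numeric series to diagnose directly.
#' @return List with `rg`, `tau_int` (frames), `pass`, and the two
#'   half-means with their confidence intervals.
#' @export
equilibration_diagnostics <- function(traj) {
  rg <- if (inherits(traj, "trajectory")) radius_of_gyration(traj)
        else as.numeric(traj)
  n <- length(rg)
  if (n < 20) stop("insufficient data: need at least 20 frames", call. = FALSE)
  ac <- stats::acf(rg, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
  stopk <- which(ac <= 0)[1]
  if (is.na(stopk)) stopk <- length(ac) + 1
  tau_int <- 1 + 2 * sum(ac[seq_len(stopk - 1)])
  tau_int <- max(tau_int, 1)
  half <- function(v) {
    m <- mean(v)
    neff <- max(2, length(v) / (2 * tau_int))
    se <- stats::sd(v) / sqrt(neff)
    c(mean = m, lo = m - 1.96 * se, hi = m + 1.96 * se)
  }
  h1 <- half(rg[seq_len(n %/% 2)])
  h2 <- half(rg[(n %/% 2 + 1):n])
  pass <- h1["lo"] <= h2["hi"] && h2["lo"] <= h1["hi"]
  list(rg = rg, tau_int = tau_int, pass = unname(pass),
       first_half = h1, second_half = h2)
}
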