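#' Kremer-Grest force field parameters
#'
#' Parameter set for the bead-spring chain: FENE bonds, WCA (purely repulsive
#' truncated-shifted Lennard-Jones) excluded volume, and a repulsive
#' confinement wall. Defaults are the canonical Kremer-Grest values
#' (`k_fene = 30 eps/sigma^2`, `R0 = 1.5 sigma`) in reduced Lennard-Jones
#' units (`sigma = eps = tau = 1`).
#'
#' @param k_fene FENE bond stiffness (eps/sigma^2).
#' @param R0 Maximum FENE bond extension (sigma); must exceed `sigma`.
#' @param eps_wca WCA energy scale (eps).
#' @param sigma Monomer diameter (sigma units; 1 by construction).
#' @param wall_eps Energy scale of the wall repulsion (eps).
#' @param wall_spacing Shell-bead spacing of the wall tiling (sigma); also
#'   sets the surface density `1 / wall_spacing^2` used by the analytic wall.
#' @param k_bend Angular stiffness (eps) of the bending term
#'   `U = k_bend (1 - cos theta)` between consecutive bonds; 0 disables it
#'   (fully flexible chain). At `kT = 1` the persistence length is roughly
#'   `k_bend` bond lengths.
#' @return Object of class `"force_field"`.
#' @export
force_field <- function(k_fene = 30, R0 = 1.5, eps_wca = 1, sigma = 1,
                        wall_eps = 1, wall_spacing = 0.25, k_bend = 0) {
  vals <- c(k_fene = k_fene, R0 = R0, eps_wca = eps_wca, sigma = sigma,
            wall_eps = wall_eps, wall_spacing = wall_spacing)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all force-field parameters must be positive", call. = FALSE)
  if (!is.finite(k_bend) || k_bend < 0)
    stop("k_bend must be non-negative", call. = FALSE)
  if (R0 <= sigma)
    stop("R0 must exceed the monomer diameter sigma", call. = FALSE)
  structure(c(as.list(vals), list(k_bend = k_bend)), class = "force_field")
}

#' Bending (angular) energy of a bead triplet
#'
#' `U = k_bend (1 - cos theta)` with `theta` the angle between consecutive
#' bond vectors (zero for a straight chain).
#'
#' @param cos_theta Cosine of the bond angle.
#' @param ff A [force_field].
#' @return Energy (eps).
#' @export
bend_energy <- function(cos_theta, ff = force_field()) {
  ff$k_bend * (1 - cos_theta)
}

#' @export
print.force_field <- function(x, ...) {
  cat(sprintf(
    "Kremer-Grest force field: k_fene=%g eps/sigma^2, R0=%g sigma, eps_wca=%g eps, sigma=%g, wall_eps=%g, wall_spacing=%g sigma\n",
    x$k_fene, x$R0, x$eps_wca, x$sigma, x$wall_eps, x$wall_spacing))
  invisible(x)
}

#' WCA pair energy and force
#'
#' `U(r) = 4 eps [(sigma/r)^12 - (sigma/r)^6] + eps` for distances below
#' the cutoff `rc = 2^(1/6) * sigma`, zero beyond; continuous (C^1) there.
#' `wca_force` returns the scalar radial force `-dU/dr` (positive =
#' repulsive, directed along the separation vector).
#'
#' @param r Center-to-center distance(s), sigma units; must be > 0.
#' @param ff A [force_field].
#' @return Energy (eps) or radial force (eps/sigma), vectorized over `r`.
#' @export
wca_energy <- function(r, ff = force_field()) {
  if (any(r <= 0)) stop("WCA energy is singular at r = 0", call. = FALSE)
  sr6 <- (ff$sigma / r)^6
  u <- 4 * ff$eps_wca * (sr6^2 - sr6) + ff$eps_wca
  ifelse(r < 2^(1 / 6) * ff$sigma, u, 0)
}

#' @rdname wca_energy
#' @export
wca_force <- function(r, ff = force_field()) {
  if (any(r <= 0)) stop("WCA force is singular at r = 0", call. = FALSE)
  sr6 <- (ff$sigma / r)^6
  f <- 24 * ff$eps_wca * (2 * sr6^2 - sr6) / r
  ifelse(r < 2^(1 / 6) * ff$sigma, f, 0)
}

#' FENE bond energy and force
#'
#' `U(r) = -0.5 k R0^2 log(1 - (r/R0)^2)`, finite extensibility with a
#' divergence at `R0`. Distances at or beyond `R0` are a model violation
#' and raise an error rather than being clamped. `fene_force` returns
#' `-dU/dr` (negative: the bond always pulls inward).
#'
#' @inheritParams wca_energy
#' @export
fene_energy <- function(r, ff = force_field()) {
  if (any(r < 0)) stop("negative bond length", call. = FALSE)
  if (any(r >= ff$R0))
    stop(sprintf("FENE bond overstretched: r >= R0 = %g sigma", ff$R0),
         call. = FALSE)
  -0.5 * ff$k_fene * ff$R0^2 * log(1 - (r / ff$R0)^2)
}

#' @rdname fene_energy
#' @export
fene_force <- function(r, ff = force_field()) {
  if (any(r < 0)) stop("negative bond length", call. = FALSE)
  if (any(r >= ff$R0))
    stop(sprintf("FENE bond overstretched: r >= R0 = %g sigma", ff$R0),
         call. = FALSE)
  -ff$k_fene * r / (1 - (r / ff$R0)^2)
}

#' Confinement wall force on a bead
#'
#' Repulsive force keeping beads inside a [spheroid]. Two modes:
#' \describe{
#'   \item{`shell_beads`}{WCA repulsion summed over a fixed quasi-uniform
#'     bead tiling of the surface (see [fibonacci_shell]); mirrors a
#'     confinement shell built from monomers.}
#'   \item{`analytic`}{the laterally integrated force of that same tiling,
#'     treated as a continuous sheet of WCA sites at density
#'     `n_A = 1 / wall_spacing^2`: magnitude `2 pi n_A d U_WCA(d)` at
#'     estimated depth `d` below the surface, applied along the inward
#'     level-set gradient. The depth estimate `d = (1 - s) / |grad s|` with
#'     `s = sqrt(f(p))` is exact for a sphere.}
#' }
#' Both modes are zero for beads deeper than `2^(1/6) sigma` inside the
#' surface and push inward everywhere else, including for beads found outside.
#'
#' @param p Position 3-vector, or n x 3 matrix.
#' @param geom A [spheroid].
#' @param ff A [force_field].
#' @param mode `"shell_beads"` or `"analytic"`.
#' @param shell Optional precomputed shell-bead matrix (to avoid rebuilding).
#' @return Force vector (3) or n x 3 matrix (eps/sigma units).
#' @export
wall_force <- function(p, geom, ff = force_field(),
                       mode = c("shell_beads", "analytic"), shell = NULL) {
  mode <- match.arg(mode)
  single <- !is.matrix(p)
  p <- if (single) matrix(p, ncol = 3) else p
  out <- matrix(0, nrow(p), 3)
  wff <- force_field(k_fene = ff$k_fene, R0 = ff$R0, eps_wca = ff$wall_eps,
                     sigma = ff$sigma, wall_eps = ff$wall_eps,
                     wall_spacing = ff$wall_spacing)
  if (mode == "shell_beads") {
    if (is.null(shell)) shell <- fibonacci_shell(geom, ff$wall_spacing)
    rc <- 2^(1 / 6) * ff$sigma
    for (i in seq_len(nrow(p))) {
      d <- sweep(shell, 2, p[i, ], "-")
      r2 <- rowSums(d * d)
      sel <- which(r2 < rc^2 & r2 > 0)
      if (length(sel)) {
        r <- sqrt(r2[sel])
        fmag <- wca_force(r, wff)               # repulsive, away from shell bead
        out[i, ] <- -colSums(d[sel, , drop = FALSE] * (fmag / r))
      }
    }
  } else {
    n_area <- 1 / ff$wall_spacing^2
    ax <- c(geom$a, geom$b, geom$c)
    rc <- 2^(1 / 6) * ff$sigma
    for (i in seq_len(nrow(p))) {
      q <- as.numeric(geom$orientation %*% (p[i, ] - geom$center))
      f <- sum((q / ax)^2)
      s <- sqrt(f)
      if (s < 1e-12) next                        # center: deep interior
      grad_s <- (q / ax^2) / s                   # body-frame gradient of s
      gnorm <- sqrt(sum(grad_s^2))
      d <- (1 - s) / gnorm                       # signed depth below surface
      d <- max(d, 0.02 * ff$sigma)               # outside beads: strong inward push
      if (d >= rc) next
      fmag <- 2 * pi * n_area * d * wca_energy(d, wff)
      dir_body <- -grad_s / gnorm                # inward
      out[i, ] <- fmag * as.numeric(t(geom$orientation) %*% dir_body)
    }
  }
  if (single) out[1, ] else out
}
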