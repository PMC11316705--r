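#' Spheroid confinement geometry
#'
#' Construct a spheroid (general ellipsoid) used as a rigid confinement for a
#' polymer chain, or as the fitted shape of a structure ensemble. Semi-axes
#' are in monomer-diameter units (sigma). For the confinements studied here
#' `b = a` and the aspect ratio `beta = c / a` distinguishes prolate
#' (`beta > 1`), spherical (`beta = 1`) and oblate (`beta < 1`) shells, with
#' `c` the semi-axis along the distinguished (z) axis.
#'
#' @param a,b,c Semi-axis lengths (sigma units); all positive. `b` defaults to
#'   `a` and `c` to `a` (a sphere).
#' @param center Numeric 3-vector, center of the spheroid.
#' @param orientation 3x3 rotation matrix whose rows are the body axes
#'   expressed in lab coordinates (orthonormal, determinant +1).
#' @return An object of class `"spheroid"` with fields `a`, `b`, `c`,
#'   `center`, `orientation`.
#' @examples
#' sph <- spheroid(5)
#' inside_spheroid(sph, c(0, 0, 0))
#' @export
spheroid <- function(a, b = a, c = a, center = c(0, 0, 0),
                     orientation = diag(3)) {
  if (!all(is.finite(c(a, b, c))) || any(c(a, b, c) <= 0))
    stop("spheroid semi-axes must be positive and finite", call. = FALSE)
  center <- as.numeric(center)
  if (length(center) != 3L) stop("center must be a 3-vector", call. = FALSE)
  orientation <- as.matrix(orientation)
  if (!identical(dim(orientation), c(3L, 3L)))
    stop("orientation must be a 3x3 matrix", call. = FALSE)
  if (max(abs(orientation %*% t(orientation) - diag(3))) > 1e-10)
    stop("orientation rows must be orthonormal (tolerance 1e-10)", call. = FALSE)
  if (det(orientation) < 0)
    stop("orientation must be a proper rotation (det +1)", call. = FALSE)
  structure(list(a = a, b = b, c = c, center = center,
                 orientation = orientation),
            class = "spheroid")
}

#' @export
print.spheroid <- function(x, ...) {
  lab <- classify_shape(sort(c(x$a, x$b, x$c)))
  cat(sprintf("Spheroid (%s): semi-axes a=%.4g b=%.4g c=%.4g sigma, beta=c/a=%.4g\n",
              lab, x$a, x$b, x$c, x$c / x$a))
  invisible(x)
}

#' Confinement size from reduced monomer density
#'
#' Solves for the spheroid semi-axes that hold `n_beads` monomers at reduced
#' density `rho_sigma3 = N / V` with aspect ratio `beta = c / a` and `b = a`:
#' `V = (4/3) pi a^2 c`, hence `a = (3 N / (4 pi rho beta))^(1/3)`. Changing
#' `beta` at fixed `N` and `rho` changes the shape but not the volume.
#'
#' @param n_beads Number of monomers (positive).
#' @param rho_sigma3 Reduced density (monomers per sigma^3, positive).
#' @param beta Aspect ratio `c / a` (positive; 1 = sphere).
#' @return A [spheroid] with `b = a`, `c = beta * a`.
#' @examples
#' axes_from_density(150, 0.25, beta = 1)  # a = (450/pi)^(1/3) ~ 5.23 sigma
#' @export
axes_from_density <- function(n_beads, rho_sigma3, beta = 1) {
  if (!all(is.finite(c(n_beads, rho_sigma3, beta))) ||
      any(c(n_beads, rho_sigma3, beta) <= 0))
    stop("n_beads, rho_sigma3 and beta must all be positive", call. = FALSE)
  a <- (3 * n_beads / (4 * pi * rho_sigma3 * beta))^(1 / 3)
  spheroid(a = a, b = a, c = beta * a)
}

#' Spheroid level-set value
#'
#' Evaluates `f(p) = sum_i (q_i / axis_i)^2` with
#' `q = orientation %*% (p - center)`; `f <= 1` inside, `f = 1` on the
#' surface.
#'
#' @param geom A [spheroid].
#' @param p Numeric 3-vector or an n x 3 matrix of positions.
#' @return Numeric vector of level-set values.
#' @export
level_set <- function(geom, p) {
  p <- if (is.matrix(p)) p else matrix(p, ncol = 3)
  q <- sweep(p, 2, geom$center) %*% t(geom$orientation)
  ax <- c(geom$a, geom$b, geom$c)
  rowSums(sweep(q, 2, ax, "/")^2)
}

#' Inside test for a spheroid
#'
#' @inheritParams level_set
#' @param tol Allowed penetration beyond the surface, in sigma along the
#'   outward direction (default 0: strict inside test).
#' @return Logical vector.
#' @export
inside_spheroid <- function(geom, p, tol = 0) {
  if (tol == 0) return(level_set(geom, p) <= 1)
  # inflate all axes by tol: conservative bound on normal penetration depth
  g2 <- geom
  g2$a <- geom$a + tol; g2$b <- geom$b + tol; g2$c <- geom$c + tol
  level_set(g2, p) <= 1
}

#' Surface area and volume of an ellipsoid
#'
#' Volume is exact, `V = (4/3) pi a b c`. Surface area uses the exact closed
#' forms for spheres and for prolate/oblate spheroids (two axes equal within
#' `spheroid_tol`, relative), and the Thomsen approximation
#' `S ~ 4 pi ((a^p b^p + a^p c^p + b^p c^p) / 3)^(1/p)` with `p = 1.6075`
#' (relative error below about 1.1%) for triaxial ellipsoids.
#'
#' @param semi_axes Numeric 3-vector of semi-axis lengths (any order).
#' @param spheroid_tol Relative tolerance for treating two axes as equal.
#' @return A list with `surface_area` and `volume`.
#' @examples
#' spheroid_surface_volume(c(1, 1, 1))  # S = 4*pi, V = 4*pi/3
#' @export
spheroid_surface_volume <- function(semi_axes, spheroid_tol = 1e-8) {
  ax <- sort(as.numeric(semi_axes))
  if (length(ax) != 3L || any(!is.finite(ax)) || any(ax <= 0))
    stop("semi_axes must be three positive numbers", call. = FALSE)
  vol <- 4 / 3 * pi * prod(ax)
  near <- function(x, y) abs(x - y) <= spheroid_tol * max(x, y)
  if (near(ax[1], ax[3])) {           # sphere
    s <- 4 * pi * ax[2]^2
  } else if (near(ax[1], ax[2])) {    # prolate: equatorial ax[1], polar ax[3]
    a <- ax[1]; cc <- ax[3]
    e <- sqrt(1 - a^2 / cc^2)
    s <- 2 * pi * a^2 * (1 + (cc / (a * e)) * asin(e))
  } else if (near(ax[2], ax[3])) {    # oblate: equatorial ax[3], polar ax[1]
    a <- ax[3]; cc <- ax[1]
    e <- sqrt(1 - cc^2 / a^2)
    s <- 2 * pi * a^2 * (1 + ((1 - e^2) / e) * atanh(e))
  } else {                            # triaxial: Thomsen approximation
    p <- 1.6075
    s <- 4 * pi * ((ax[1]^p * ax[2]^p + ax[1]^p * ax[3]^p +
                      ax[2]^p * ax[3]^p) / 3)^(1 / p)
  }
  list(surface_area = s, volume = vol)
}

#' Sphericity of a solid
#'
#' `Phi = pi^(1/3) * (6 * volume)^(2/3) / surface_area`: the ratio of the
#' surface area of a sphere with the solid's volume to the solid's surface
#' area. Ranges over (0, 1], with 1 attained only by the sphere.
#'
#' @param volume Volume (length^3), positive.
#' @param surface_area Surface area (length^2), positive.
#' @return Sphericity value.
#' @examples
#' sphericity(4 * pi / 3, 4 * pi)  # unit sphere -> 1
#' @export
sphericity <- function(volume, surface_area) {
  if (!all(is.finite(c(volume, surface_area))) ||
      volume <= 0 || surface_area <= 0)
    stop("volume and surface_area must be positive", call. = FALSE)
  pi^(1 / 3) * (6 * volume)^(2 / 3) / surface_area
}

#' Quasi-uniform bead tiling of a spheroid surface
#'
#' Places points by a Fibonacci-sphere lattice on the unit sphere, scaled by
#' the semi-axes and rotated/translated into the lab frame. The point count is
#' chosen from the area of a sphere with the *largest* semi-axis so that the
#' local spacing stays at or below `spacing` everywhere despite the
#' anisotropic stretch of the mapping.
#'
#' @param geom A [spheroid].
#' @param spacing Target maximum inter-bead spacing (sigma).
#' @return An n x 3 matrix of shell-bead positions.
#' @export
fibonacci_shell <- function(geom, spacing = 0.25) {
  stopifnot(inherits(geom, "spheroid"), spacing > 0)
  rmax <- max(geom$a, geom$b, geom$c)
  n <- max(32L, as.integer(ceiling(4 * pi * rmax^2 / spacing^2)))
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i          # golden-angle longitude
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  pts <- cbind(r * cos(phi) * geom$a, r * sin(phi) * geom$b, z * geom$c)
  sweep(pts %*% geom$orientation, 2, geom$center, "+")
}
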