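#' Principal axes of a point cloud
#'
#' Centers the cloud and eigendecomposes its covariance. Semi-axis lengths
#' use the uniform-ellipsoid moment identity `<q_i^2> = axis_i^2 / 5`, i.e.
#' `axis_i = sqrt(5 * eigenvalue_i)`: the semi-axes of the uniform-density
#' ellipsoid with the same second moments as the cloud.
#'
#' @param coords M x 3 coordinate matrix (M >= 4).
#' @return List with `center` (3-vector), `orientation` (3 x 3, rows =
#'   principal axes, descending eigenvalue, determinant +1) and
#'   `axis_lengths` (descending).
#' @export
pca_axes <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 4) stop("need at least 4 points", call. = FALSE)
  ctr <- colMeans(coords)
  xc <- sweep(coords, 2, ctr)
  cv <- crossprod(xc) / nrow(xc)
  eg <- eigen(cv, symmetric = TRUE)
  rk <- sum(eg$values > max(eg$values) * 1e-10)
  if (rk < 3)
    stop(sprintf("degenerate geometry: point cloud has rank %d", rk),
         call. = FALSE)
  rot <- t(eg$vectors)             # rows = principal axes
  if (det(rot) < 0) rot[3, ] <- -rot[3, ]
  list(center = ctr, orientation = rot,
       axis_lengths = sqrt(5 * eg$values))
}

#' Fit a spheroid to a structure
#'
#' Fits an ellipsoid to the bead cloud of one chromosome structure and
#' derives its sphericity and shape class. The default (and robust) method
#' matches second moments via [pca_axes]; `method = "surface"` refines the
#' three semi-axes by least squares on the level-set residuals
#' `sum_i (q_i/axis_i)^2 - 1` of the outer shell of points (those beyond the
#' 75th percentile of the PCA-frame radius), keeping the PCA orientation.
#'
#' @param coords M x 3 coordinate matrix.
#' @param method `"pca"` (moments) or `"surface"` (least-squares refinement).
#' @param tol Relative axis tolerance passed to [classify_shape].
#' @return Object of class `"shape_fit"`: `semi_axes` (ascending a <= b <= c),
#'   `orientation`, `center`, `phi` (sphericity), `label`, `beta`.
#' @export
fit_spheroid <- function(coords, method = c("pca", "surface"), tol = 0.15) {
  method <- match.arg(method)
  p <- pca_axes(coords)
  ax <- p$axis_lengths
  if (method == "surface") {
    q <- sweep(as.matrix(coords), 2, p$center) %*% t(p$orientation)
    s <- sqrt(rowSums(sweep(q, 2, ax, "/")^2))
    sh <- q[s >= stats::quantile(s, 0.75), , drop = FALSE]
    obj <- function(lax) {
      a <- exp(lax)
      mean((rowSums(sweep(sh, 2, a, "/")^2) - 1)^2)
    }
    ax <- exp(stats::optim(log(ax), obj, method = "Nelder-Mead")$par)
  }
  ord <- order(ax)                     # ascending a <= b <= c
  semi <- ax[ord]
  orient <- p$orientation[rev(ord), , drop = FALSE]  # keep descending-axis rows
  sv <- spheroid_surface_volume(semi)
  phi <- min(sphericity(sv$volume, sv$surface_area), 1)
  label <- classify_shape(semi, tol = tol)
  beta <- switch(label,
                 prolate = semi[3] / mean(semi[1:2]),
                 oblate  = semi[1] / mean(semi[2:3]),
                 sphere  = semi[3] / semi[1])
  structure(list(semi_axes = semi, orientation = orient, center = p$center,
                 phi = phi, label = label, beta = beta, method = method),
            class = "shape_fit")
}

#' @export
print.shape_fit <- function(x, ...) {
  cat(sprintf(
    "Spheroid fit (%s): semi-axes (%.3g, %.3g, %.3g), %s, beta=%.3g, sphericity=%.4f\n",
    x$method, x$semi_axes[1], x$semi_axes[2], x$semi_axes[3], x$label,
    x$beta, x$phi))
  invisible(x)
}

#' @export
coef.shape_fit <- function(object, ...) {
  c(a = object$semi_axes[1], b = object$semi_axes[2], c = object$semi_axes[3],
    phi = object$phi, beta = object$beta)
}

#' Classify a fitted shape as sphere, prolate or oblate
#'
#' With sorted semi-axes `a <= b <= c`: sphere when `c/a <= 1 + tol`;
#' otherwise prolate when the long axis is the distinguished one
#' (`c - b >= b - a`), else oblate.
#'
#' @param x Sorted semi-axis triple, or a `"shape_fit"`.
#' @param tol Relative tolerance for the sphere class.
#' @return `"sphere"`, `"prolate"` or `"oblate"`.
#' @export
classify_shape <- function(x, tol = 0.15) {
  ax <- if (inherits(x, "shape_fit")) x$semi_axes else as.numeric(x)
  if (is.unsorted(ax)) stop("semi-axes must be sorted ascending", call. = FALSE)
  if (ax[3] / ax[1] <= 1 + tol) return("sphere")
  if ((ax[3] - ax[2]) >= (ax[2] - ax[1])) "prolate" else "oblate"
}

#' Rescale a contact profile onto a shared grid
#'
#' Maps the profile's scaled separations `l = k / N` onto a common grid in
#' (0, 1] by linear interpolation, so chromosomes of different bead counts
#' become comparable. Grid nodes outside the source support are returned as
#' `NA` (masked), never extrapolated.
#'
#' @param profile A `"contact_profile"` (columns `l`, `p_c`).
#' @param grid Target grid, strictly inside (0, 1].
#' @return A `"contact_profile"`-like data frame with columns `l`, `p_c`.
#' @export
rescale_profile <- function(profile, grid) {
  grid <- as.numeric(grid)
  if (any(grid <= 0) || any(grid > 1))
    stop("grid must lie in (0, 1]", call. = FALSE)
  if (nrow(profile) < 2) stop("profile too short to interpolate", call. = FALSE)
  v <- stats::approx(profile$l, profile$p_c, xout = grid, rule = 1)$y
  out <- data.frame(l = grid, p_c = v)
  class(out) <- c("contact_profile", "data.frame")
  out
}

#' Cross-chromosome normalization of rescaled contact curves
#'
#' Two-step normalization enabling the comparison of contact enrichment
#' across chromosomes of different lengths: (1) divide each curve pointwise
#' by the cross-chromosome mean curve at the corresponding rescaled length,
#' removing the generic distance decay; (2) scale each curve so that the
#' trapezoidal area under it (over its unmasked support) equals 1,
#' equalizing total contact counts.
#'
#' @param curves Named list of data frames with columns `l`, `p_c` on the
#'   same grid (as from [rescale_profile]), or a matrix with chromosomes in
#'   columns plus a `grid` attribute.
#' @param grid Shared grid (required when `curves` is a plain matrix).
#' @return List with `grid`, `normalized` (matrix, chromosomes in columns;
#'   `NA` at masked nodes) and `mean_curve`.
#' @export
normalize_across_chromosomes <- function(curves, grid = NULL) {
  if (is.list(curves) && !is.data.frame(curves)) {
    if (length(curves) < 2) stop("need at least 2 chromosomes", call. = FALSE)
    grid <- curves[[1]]$l
    for (cv in curves)
      if (!isTRUE(all.equal(cv$l, grid)))
        stop("all profiles must share the same grid", call. = FALSE)
    m <- vapply(curves, function(cv) cv$p_c, numeric(length(grid)))
    if (is.null(colnames(m)) && !is.null(names(curves)))
      colnames(m) <- names(curves)
  } else {
    m <- as.matrix(curves)
    if (is.null(grid)) stop("grid required for matrix input", call. = FALSE)
    if (ncol(m) < 2) stop("need at least 2 chromosomes", call. = FALSE)
  }
  mean_curve <- rowMeans(m, na.rm = TRUE)
  zero <- !is.na(mean_curve) & mean_curve == 0
  if (any(zero)) {
    warning(sprintf("mean curve is zero at %d grid node(s); masked", sum(zero)))
    mean_curve[zero] <- NA_real_
  }
  ratio <- sweep(m, 1, mean_curve, "/")
  norm <- apply(ratio, 2, function(y) {
    ok <- !is.na(y)
    if (sum(ok) < 2) return(y * NA_real_)
    area <- sum(diff(grid[ok]) * (y[ok][-1] + y[ok][-sum(ok)]) / 2)
    y / area
  })
  list(grid = grid, normalized = norm, mean_curve = mean_curve)
}

#' Per-chromosome shape report
#'
#' Summarizes an ensemble of structure replicas per chromosome: the fraction
#' of replicas in each shape class, the mean sphericity and the mean aspect
#' ratio, sorted by mean sphericity.
#'
#' @param ensembles Named list; each element is a list of M x 3 coordinate
#'   matrices (the replicas of one chromosome).
#' @param tol Shape-class tolerance (see [classify_shape]).
#' @param method Fitting method (see [fit_spheroid]).
#' @return Data frame with columns `chromosome`, `n_replicas`, `frac_sphere`,
#'   `frac_oblate`, `frac_prolate`, `mean_phi`, `mean_beta`.
#' @export
shape_report <- function(ensembles, tol = 0.15, method = "pca") {
  stopifnot(length(ensembles) >= 1)
  if (is.null(names(ensembles)))
    names(ensembles) <- paste0("chr", seq_along(ensembles))
  rows <- lapply(names(ensembles), function(nm) {
    fits <- lapply(ensembles[[nm]], fit_spheroid, method = method, tol = tol)
    labs <- vapply(fits, `[[`, "", "label")
    data.frame(chromosome = nm, n_replicas = length(fits),
               frac_sphere = mean(labs == "sphere"),
               frac_oblate = mean(labs == "oblate"),
               frac_prolate = mean(labs == "prolate"),
               mean_phi = mean(vapply(fits, `[[`, 0, "phi")),
               mean_beta = mean(vapply(fits, `[[`, 0, "beta")))
  })
  out <- do.call(rbind, rows)
  out[order(out$mean_phi), , drop = FALSE]
}
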