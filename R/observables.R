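#' Frames retained by the "last fraction" averaging convention
#' @noRd
.retained_frames <- function(frames, last_fraction) {
  nf <- dim(frames)[3]
  if (is.na(nf) || nf < 1) stop("empty trajectory", call. = FALSE)
  if (!(last_fraction > 0 && last_fraction <= 1))
    stop("last_fraction must be in (0, 1]", call. = FALSE)
  keep <- ceiling(last_fraction * nf)
  frames[, , (nf - keep + 1):nf, drop = FALSE]
}

.as_frame_stack <- function(x) {
  if (inherits(x, "trajectory")) return(x$frames)
  if (is.matrix(x)) return(array(x, c(nrow(x), 3, 1)))
  x
}

#' Mean-squared internal distances
#'
#' For each contour separation `k = 1 .. N-1`, the average of
#' `|r_i - r_(i+k)|^2` over all monomer pairs and over the last
#' `last_fraction` of the saved frames (the equilibrated tail of the run),
#' reported against the scaled contour separation `l = k / N`.
#'
#' @param traj A `"trajectory"` (or single N x 3 conformation).
#' @param last_fraction Fraction of trailing frames to average over.
#' @return A `"distance_profile"` data frame with columns `k`, `l`,
#'   `r2_mean` (sigma^2) and `n_pairs`.
#' @export
mean_squared_internal_distance <- function(traj, last_fraction = 0.1) {
  frames <- .retained_frames(.as_frame_stack(traj), last_fraction)
  N <- dim(frames)[1]; nf <- dim(frames)[3]
  ps <- pair_profile_cpp(frames, 0)   # cutoff irrelevant for r2 sums
  k <- seq_len(N - 1)
  n_pairs <- (N - k) * nf
  out <- data.frame(k = k, l = k / N, r2_mean = ps$r2_sum / n_pairs,
                    n_pairs = n_pairs)
  class(out) <- c("distance_profile", "data.frame")
  attr(out, "n_beads") <- N
  attr(out, "n_frames") <- nf
  out
}

#' Contact probability versus scaled contour separation
#'
#' Two monomers are in contact when their center-to-center distance is
#' strictly smaller than `r_cutoff` (default `2 sigma`). For each contour
#' separation `k >= min_separation` the fraction of (frame, i, j) pairs with
#' `|i - j| = k` in contact is reported against `l = k / N`. Bonded
#' neighbours (`k = 1`) are always within the cutoff and carry no
#' information, hence the default `min_separation = 2`.
#'
#' @param traj A `"trajectory"` (or single N x 3 conformation).
#' @param r_cutoff Contact distance threshold (sigma); must exceed sigma.
#' @param min_separation Smallest contour separation reported.
#' @param last_fraction Fraction of trailing frames used.
#' @return A `"contact_profile"` data frame with columns `k`, `l`, `p_c`,
#'   `contacts`, `n_pairs`; attribute `r_cutoff`.
#' @export
contact_probability <- function(traj, r_cutoff = 2, min_separation = 2,
                                last_fraction = 0.1) {
  if (r_cutoff <= 1) stop("r_cutoff must exceed the monomer diameter",
                          call. = FALSE)
  frames <- .retained_frames(.as_frame_stack(traj), last_fraction)
  N <- dim(frames)[1]; nf <- dim(frames)[3]
  ps <- pair_profile_cpp(frames, r_cutoff)
  k <- seq_len(N - 1)
  keep <- k >= min_separation
  n_pairs <- (N - k) * nf
  out <- data.frame(k = k[keep], l = k[keep] / N,
                    p_c = (ps$contacts / n_pairs)[keep],
                    contacts = ps$contacts[keep], n_pairs = n_pairs[keep])
  class(out) <- c("contact_profile", "data.frame")
  attr(out, "r_cutoff") <- r_cutoff
  attr(out, "n_beads") <- N
  attr(out, "n_frames") <- nf
  out
}

#' Pool contact profiles across replicas
#'
#' Sums raw contact and pair counts over replica profiles sharing one grid,
#' then recomputes `p_c`; this is the "pool counts, then fit" replica mode.
#'
#' @param profiles List of `"contact_profile"` objects on identical grids.
#' @return A pooled `"contact_profile"`.
#' @export
pool_profiles <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  base <- profiles[[1]]
  for (p in profiles[-1]) {
    if (!isTRUE(all.equal(p$l, base$l)))
      stop("profiles must share the same l grid", call. = FALSE)
    base$contacts <- base$contacts + p$contacts
    base$n_pairs <- base$n_pairs + p$n_pairs
  }
  base$p_c <- base$contacts / base$n_pairs
  base
}

#' Fit the contact-probability scaling exponent
#'
#' Unweighted ordinary least squares of `log p_c` on `log l` over the window
#' `l_min < l < l_max` (strict), using only grid points with `p_c > 0`.
#' The exponent of the power law `p_c(l) ~ l^(-alpha)` is minus the slope.
#' The default window (0.07, 0.2) targets the decade where confinement-shape
#' differences are visible but the large-l plateau has not yet set in.
#'
#' @param profile A `"contact_profile"` (or data frame with `l` and `p_c`).
#' @param l_min,l_max Fit window (strict inequalities).
#' @param log_bins Optional number of logarithmically spaced bins; points in
#'   the window are averaged per bin before fitting (useful for noisy
#'   large-`l` tails). `NULL` (default) fits the raw grid points.
#' @return Object of class `"scaling_fit"`: `alpha`, `stderr`, `r_squared`,
#'   `l_min`, `l_max`, `n_points`, and the underlying `lm` fit.
#' @export
fit_scaling_exponent <- function(profile, l_min = 0.07, l_max = 0.2,
                                 log_bins = NULL) {
  sel <- profile$l > l_min & profile$l < l_max & profile$p_c > 0
  if (sum(sel) < 3)
    stop("insufficient data: need at least 3 usable points in the window",
         call. = FALSE)
  ll <- profile$l[sel]
  pp <- profile$p_c[sel]
  if (!is.null(log_bins)) {
    edges <- exp(seq(log(min(ll)) - 1e-12, log(max(ll)) + 1e-12,
                     length.out = log_bins + 1))
    bin <- cut(ll, edges, include.lowest = TRUE)
    # geometric means: unbiased for pure power laws
    ll <- tapply(ll, bin, function(v) exp(mean(log(v))))
    pp <- tapply(pp, bin, function(v) exp(mean(log(v))))
    keep <- !is.na(ll) & !is.na(pp)
    ll <- ll[keep]; pp <- pp[keep]
    if (length(ll) < 3)
      stop("insufficient data after log-binning", call. = FALSE)
  }
  d <- data.frame(x = log(ll), y = log(pp))
  fit <- stats::lm(y ~ x, data = d)
  sm <- summary(fit)
  structure(list(alpha = -unname(stats::coef(fit)[2]),
                 stderr = sm$coefficients[2, 2],
                 r_squared = sm$r.squared,
                 intercept = unname(stats::coef(fit)[1]),
                 l_min = l_min, l_max = l_max, n_points = length(ll),
                 lm = fit),
            class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf(
    "Contact-probability scaling fit: p_c(l) ~ l^(-alpha)\n  alpha = %.4f (SE %.4f), window %g < l < %g, %d points, R^2 = %.4f\n",
    x$alpha, x$stderr, x$l_min, x$l_max, x$n_points, x$r_squared))
  invisible(x)
}

#' @export
summary.scaling_fit <- function(object, ...) {
  print(object)
  cat("\nUnderlying log-log regression:\n")
  print(summary(object$lm))
  invisible(object)
}

#' @export
coef.scaling_fit <- function(object, ...) {
  c(alpha = object$alpha, log_amplitude = object$intercept)
}

#' @export
predict.scaling_fit <- function(object, l, ...) {
  exp(object$intercept) * l^(-object$alpha)
}

#' Per-seed and pooled exponents over a replica set
#'
#' @param profiles List of replica `"contact_profile"`s on a shared grid.
#' @param l_min,l_max Fit window passed to [fit_scaling_exponent].
#' @return List with `pooled` (fit on summed counts), `per_seed` (vector of
#'   per-replica alphas) and `ci95` (t-interval over per-replica alphas).
#' @export
replica_scaling <- function(profiles, l_min = 0.07, l_max = 0.2) {
  pooled <- fit_scaling_exponent(pool_profiles(profiles), l_min, l_max)
  per <- vapply(profiles, function(p)
    fit_scaling_exponent(p, l_min, l_max)$alpha, numeric(1))
  n <- length(per)
  ci <- if (n >= 2) {
    se <- stats::sd(per) / sqrt(n)
    mean(per) + c(-1, 1) * stats::qt(0.975, n - 1) * se
  } else c(NA_real_, NA_real_)
  list(pooled = pooled, per_seed = per, ci95 = ci)
}

#' Normalized end-to-end distance distribution at fixed contour separation
#'
#' Histogram of `x = sqrt(R^2(k)) / sqrt(<R^2(k)>)` over all monomer pairs at
#' contour separation `k` and the retained trailing frames, normalized to
#' unit area. By construction the mean of `x^2` is 1.
#'
#' @param traj A `"trajectory"`.
#' @param k Contour separation (beads).
#' @param n_bins Number of histogram bins.
#' @param last_fraction Fraction of trailing frames used.
#' @return List with `breaks`, `mids`, `density`, `x` (the raw normalized
#'   distances) and `mean_r2` (sigma^2).
#' @export
distance_distribution <- function(traj, k = 10, n_bins = 40,
                                  last_fraction = 0.1) {
  frames <- .retained_frames(.as_frame_stack(traj), last_fraction)
  N <- dim(frames)[1]
  if (k < 1 || k >= N) stop("k must be in [1, N-1]", call. = FALSE)
  nf <- dim(frames)[3]
  r <- numeric(0)
  for (f in seq_len(nf)) {
    x <- frames[, , f]
    d <- x[seq_len(N - k), , drop = FALSE] - x[(k + 1):N, , drop = FALSE]
    r <- c(r, sqrt(rowSums(d^2)))
  }
  mean_r2 <- mean(r^2)
  xn <- r / sqrt(mean_r2)
  h <- graphics::hist(xn, breaks = seq(0, max(xn) * (1 + 1e-9),
                                       length.out = n_bins + 1), plot = FALSE)
  list(breaks = h$breaks, mids = h$mids, density = h$density, x = xn,
       mean_r2 = mean_r2, k = k, l = k / N)
}

#' @export
plot.contact_profile <- function(x, ..., log = "xy") {
  graphics::plot(x$l, x$p_c, log = log, xlab = "scaled separation l",
                 ylab = expression(p[c](l)), type = "b", pch = 16, ...)
  invisible(x)
}

#' @export
plot.distance_profile <- function(x, ..., log = "xy") {
  graphics::plot(x$l, x$r2_mean, log = log, xlab = "scaled separation l",
                 ylab = expression(group("<", R^2(l), ">")), type = "b",
                 pch = 16, ...)
  invisible(x)
}
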