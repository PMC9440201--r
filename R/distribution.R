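#' Distance grid for P(r)
#'
#' Uniform grid of inter-label distances on which distance distributions are
#' discretized. The default 1.5--8 nm range covers the distances accessible
#' to four-pulse DEER with nitroxide labels.
#'
#' @param r_min,r_max Grid limits in nm (`r_min > 0`).
#' @param step Grid spacing in nm.
#' @return An object of class `distance_grid` with fields `r_min`, `r_max`,
#'   `step` and `values` (the ordered distances).
#' @export
#' @examples
#' g <- distance_grid(2, 6, 0.1)
#' range(g$values)
distance_grid <- function(r_min = 1.5, r_max = 8.0, step = 0.02) {
  stopifnot_scalar(r_min, "r_min", lower = 1e-12)
  stopifnot_scalar(step, "step", lower = 1e-12)
  stopifnot_scalar(r_max, "r_max", lower = r_min + step)
  values <- seq(r_min, r_max, by = step)
  if (r_max - values[length(values)] > step / 2 + 1e-12)
    values <- c(values, r_max)
  structure(list(r_min = r_min, r_max = r_max, step = step, values = values),
            class = "distance_grid")
}

is_distance_grid <- function(x) inherits(x, "distance_grid")

#' Gaussian components of a distance distribution
#'
#' @param r0 Component centers, nm (`> 0`).
#' @param sigma Component widths (standard deviations), nm (`> 0`).
#' @param a Component populations (fractions). Normalized to sum to 1 when
#'   `normalize = TRUE` (the default); otherwise they must already sum to 1.
#' @param normalize Normalize populations to unit sum?
#' @return A data.frame of class `gaussian_components` with columns
#'   `r0`, `sigma`, `a`, sorted by center.
#' @export
gaussian_components <- function(r0, sigma, a = rep(1 / length(r0), length(r0)),
                                normalize = TRUE) {
  if (length(r0) != length(sigma) || length(r0) != length(a))
    stop("r0, sigma and a must have equal length", call. = FALSE)
  if (any(!is.finite(r0)) || any(r0 <= 0)) stop("centers r0 must be positive", call. = FALSE)
  if (any(!is.finite(sigma)) || any(sigma <= 0)) stop("widths sigma must be positive", call. = FALSE)
  if (any(!is.finite(a)) || any(a < 0)) stop("populations a must be nonnegative", call. = FALSE)
  s <- sum(a)
  if (normalize) {
    if (s <= 0) stop("populations sum to zero", call. = FALSE)
    a <- a / s
  } else if (abs(s - 1) > 1e-6) {
    stop("populations must sum to 1 (got ", format(s), ")", call. = FALSE)
  }
  ord <- order(r0)
  out <- data.frame(r0 = r0[ord], sigma = sigma[ord], a = a[ord])
  class(out) <- c("gaussian_components", "data.frame")
  out
}

# Sum-of-Gaussians density evaluated on a distance axis (not yet
# grid-renormalized).
mixture_density <- function(r, components) {
  dens <- numeric(length(r))
  for (k in seq_len(nrow(components)))
    dens <- dens + components$a[k] *
      stats::dnorm(r, mean = components$r0[k], sd = components$sigma[k])
  dens
}

#' Distance distribution P(r)
#'
#' A probability density of inter-label distance discretized on a
#' [distance_grid()], optionally carrying its sum-of-Gaussians
#' parameterization. The stored density is renormalized so its trapezoidal
#' integral over the grid equals 1.
#'
#' @param grid A [distance_grid()].
#' @param density Nonnegative density values on `grid$values` (1/nm). Either
#'   `density` or `components` must be given.
#' @param components A [gaussian_components()] object; when supplied without
#'   `density`, the density is the renormalized component sum on the grid.
#' @return An object of class `distance_distribution` with fields `grid`,
#'   `density` and `components` (possibly `NULL`).
#' @export
#' @examples
#' P <- distance_distribution(distance_grid(),
#'   components = gaussian_components(c(3, 4.5), c(0.3, 0.3), c(0.7, 0.3)))
#' sum(P$density * diff(P$grid$values[1:2]))  # ~1
distance_distribution <- function(grid, density = NULL, components = NULL) {
  if (!is_distance_grid(grid)) stop("`grid` must be a distance_grid", call. = FALSE)
  if (is.null(density)) {
    if (is.null(components)) stop("supply `density` or `components`", call. = FALSE)
    density <- mixture_density(grid$values, components)
  } else {
    if (length(density) != length(grid$values))
      stop("density length must match grid", call. = FALSE)
    if (any(!is.finite(density)) || any(density < -1e-12))
      stop("density must be finite and nonnegative", call. = FALSE)
    density <- pmax(density, 0)
  }
  w <- trapz_weights(grid$values)
  mass <- sum(w * density)
  if (mass <= 0) stop("density integrates to zero on the grid", call. = FALSE)
  structure(list(grid = grid, density = density / mass, components = components),
            class = "distance_distribution")
}

is_distance_distribution <- function(x) inherits(x, "distance_distribution")

#' @export
print.distance_distribution <- function(x, ...) {
  w <- trapz_weights(x$grid$values)
  m <- sum(w * x$grid$values * x$density)
  cat(sprintf("<distance_distribution> grid %.2f-%.2f nm (step %.3g), mean %.2f nm",
              x$grid$r_min, x$grid$r_max, x$grid$step, m))
  if (!is.null(x$components))
    cat(sprintf(", %d Gaussian component(s)", nrow(x$components)))
  cat("\n")
  invisible(x)
}

#' Summary statistics of a distance distribution
#'
#' @param P A [distance_distribution()].
#' @return Named vector with the trapezoidal `mean`, `sd` and `mode` (nm).
#' @export
distribution_moments <- function(P) {
  stopifnot(is_distance_distribution(P))
  r <- P$grid$values
  w <- trapz_weights(r)
  m <- sum(w * r * P$density)
  v <- sum(w * (r - m)^2 * P$density)
  c(mean = m, sd = sqrt(max(v, 0)), mode = r[which.max(P$density)])
}

#' Overlap coefficient between two distance distributions
#'
#' Computes the overlap coefficient, the integral of the pointwise minimum
#' of the two densities. Equals 1 for identical distributions and 0 for
#' distributions with disjoint support. Used to score agreement between a
#' structure-predicted and an experimentally fitted P(r).
#'
#' @param P_pred,P_exp [distance_distribution()] objects. If their grids
#'   differ, `P_exp` is linearly interpolated onto the grid of `P_pred`
#'   (zero outside its own support) and renormalized.
#' @return Overlap coefficient in `[0, 1]`.
#' @export
distribution_overlap <- function(P_pred, P_exp) {
  if (!is_distance_distribution(P_pred) || !is_distance_distribution(P_exp))
    stop("inputs must be distance_distribution objects", call. = FALSE)
  r <- P_pred$grid$values
  p1 <- P_pred$density
  if (isTRUE(all.equal(P_exp$grid$values, r, tolerance = 1e-9))) {
    p2 <- P_exp$density
  } else {
    p2 <- stats::approx(P_exp$grid$values, P_exp$density, xout = r,
                        yleft = 0, yright = 0)$y
    w <- trapz_weights(r)
    mass <- sum(w * p2)
    if (mass < 0.5)
      stop("grids barely overlap; resampled density lost most of its mass",
           call. = FALSE)
    p2 <- p2 / mass
  }
  w <- trapz_weights(r)
  for (p in list(p1, p2)) {
    if (abs(sum(w * p) - 1) > 1e-3)
      stop("inputs must be normalized densities", call. = FALSE)
  }
  min(max(sum(w * pmin(p1, p2)), 0), 1)
}
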