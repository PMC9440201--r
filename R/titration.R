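#' Generalized Hill titration curve
#'
#' \deqn{f(\mathrm{pH}) = f_\mathrm{base} + \frac{f_\mathrm{acid} -
#'   f_\mathrm{base}}{1 + 10^{\,n\,(\mathrm{pH} - \mathrm{p}K)}}.}
#' At `pH = pK` the curve sits exactly halfway between the plateaus; `n = 1`
#' is a single-site (Henderson-Hasselbalch) protonation equilibrium, while
#' `n > 1` indicates cooperative proton binding.
#'
#' @param pH pH values.
#' @param pK Transition midpoint (pH units).
#' @param n Hill coefficient (> 0).
#' @param f_acid,f_base Plateau populations at acidic / basic pH.
#' @return Population fraction at each pH.
#' @export
hill_curve <- function(pH, pK, n = 1, f_acid = 1, f_base = 0) {
  f_base + (f_acid - f_base) / (1 + 10^(n * (pH - pK)))
}

#' Titration series of state populations
#'
#' @param pH pH values (>= 4 distinct).
#' @param f Population fraction of the tracked state, in `[0, 1]`.
#' @param sigma2 Optional 2-sigma uncertainty per point (>= 0). All-zero or
#'   `NULL` means an unweighted fit downstream.
#' @param direction `"rising"`, `"decreasing"`, or `"auto"` (sign of the
#'   trend of `f` against pH).
#' @return Object of class `titration_series` (a data.frame with attributes).
#' @export
titration_series <- function(pH, f, sigma2 = NULL, direction = c("auto", "rising", "decreasing")) {
  direction <- match.arg(direction)
  if (length(unique(pH)) < 4L)
    stop("need at least 4 distinct pH values", call. = FALSE)
  if (length(f) != length(pH) || any(!is.finite(f)) || any(f < -1e-9) || any(f > 1 + 1e-9))
    stop("f must match pH in length and lie in [0, 1]", call. = FALSE)
  f <- pmin(pmax(f, 0), 1)
  if (is.null(sigma2)) sigma2 <- rep(0, length(pH))
  if (length(sigma2) != length(pH) || any(sigma2 < 0))
    stop("sigma2 must be nonnegative and match pH in length", call. = FALSE)
  if (direction == "auto") {
    slope <- stats::coef(stats::lm(f ~ pH))[2]
    direction <- if (slope >= 0) "rising" else "decreasing"
  }
  out <- data.frame(pH = pH, f = f, sigma2 = sigma2)
  out <- out[order(out$pH), ]
  rownames(out) <- NULL
  attr(out, "direction") <- direction
  class(out) <- c("titration_series", "data.frame")
  out
}

#' Fit the Hill model to a titration series
#'
#' Weighted nonlinear least squares of [hill_curve()] against measured
#' state populations. Weights are inverse-variance from the per-point
#' 2-sigma uncertainties; when all uncertainties are zero the fit is
#' unweighted. Equal uncertainties reproduce the unweighted fit exactly.
#'
#' @param series A [titration_series()] (or data.frame with `pH`, `f`,
#'   optional `sigma2`).
#' @param fix_n Optional fixed Hill coefficient (e.g. `1` for independent
#'   protonation); `NULL` (default) fits n freely.
#' @return Object of class `titration_fit`: `pK`, `n`, `f_acid`, `f_base`,
#'   their 2-sigma uncertainties, `rss`, `fitted` values and the series.
#' @export
#' @examples
#' s <- titration_series(seq(4, 9, length.out = 9),
#'                       hill_curve(seq(4, 9, length.out = 9), 6.5, 1, 0.8, 0.2))
#' hill_fit(s)$pK
hill_fit <- function(series, fix_n = NULL) {
  if (!inherits(series, "titration_series"))
    series <- titration_series(series$pH, series$f, series$sigma2)
  pH <- series$pH; f <- series$f
  rng <- max(f) - min(f)
  if (rng < 0.02)
    stop("no transition in the sampled pH range (population nearly constant); ",
         "pK and n are unidentifiable", call. = FALSE)
  sig <- series$sigma2 / 2
  weighted <- any(sig > 0)
  if (weighted && any(sig <= 0))
    sig[sig <= 0] <- min(sig[sig > 0])   # guard stray zero-uncertainty points
  scale <- if (weighted) sig else rep(1, length(f))
  rising <- attr(series, "direction") == "rising"
  # start values: plateaus from the pH extremes, pK from the half-height
  f_lo_pH <- mean(f[pH <= stats::quantile(pH, 0.25)])
  f_hi_pH <- mean(f[pH >= stats::quantile(pH, 0.75)])
  mid <- (f_lo_pH + f_hi_pH) / 2
  pK0 <- pH[which.min(abs(f - mid))]
  free_n <- is.null(fix_n)
  par0 <- c(pK = pK0, if (free_n) c(n = 1), f_acid = f_lo_pH, f_base = f_hi_pH)
  lower <- c(min(pH) - 2, if (free_n) 0.05, 0, 0)
  upper <- c(max(pH) + 2, if (free_n) 10, 1, 1)
  resid_fn <- function(p) {
    n_use <- if (free_n) p[2] else fix_n
    (hill_curve(pH, p[1], n_use, p[length(p) - 1], p[length(p)]) - f) / scale
  }
  fit <- minpack.lm::nls.lm(par = par0, lower = lower, upper = upper,
                            fn = resid_fn,
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  p <- fit$par
  n_hat <- if (free_n) unname(p[2]) else fix_n
  fitted_f <- hill_curve(pH, p[1], n_hat, p[length(p) - 1], p[length(p)])
  rss <- sum((fitted_f - f)^2)
  J <- num_jacobian(resid_fn, p)
  vc <- tryCatch(solve(crossprod(J)), error = function(e)
    matrix(NA_real_, length(p), length(p)))
  if (!weighted) {
    dof <- max(length(f) - length(p), 1)
    vc <- vc * rss / dof
  }
  se <- sqrt(pmax(diag(vc), 0))
  names(se) <- names(p)
  structure(list(
    pK = unname(p[1]), n = n_hat,
    f_acid = unname(p[length(p) - 1]), f_base = unname(p[length(p)]),
    pK_2sigma = 2 * unname(se[1]),
    n_2sigma = if (free_n) 2 * unname(se[2]) else 0,
    f_acid_2sigma = 2 * unname(se[length(p) - 1]),
    f_base_2sigma = 2 * unname(se[length(p)]),
    n_fixed = !free_n, direction = attr(series, "direction"),
    rss = rss, fitted = fitted_f, series = series,
    converged = fit$info %in% 1:4), class = "titration_fit")
}

#' @export
print.titration_fit <- function(x, ...) {
  cat(sprintf("<titration_fit> pK = %.2f +/- %.2f (2s), n = %.2f%s, plateaus %.2f -> %.2f\n",
              x$pK, x$pK_2sigma, x$n, if (x$n_fixed) " (fixed)" else
                sprintf(" +/- %.2f (2s)", x$n_2sigma), x$f_acid, x$f_base))
  invisible(x)
}

#' Assemble a titration series from fitted DEER populations
#'
#' Pulls the population of one distance component, per pH condition, out of
#' global fit results and assembles them (with their 2-sigma uncertainties)
#' into a [titration_series()] ready for [hill_fit()].
#'
#' @param fits A single `deer_global_fit` whose conditions carry `meta$pH`,
#'   or a list of fits each tagged with one pH (`meta$pH` on their traces).
#' @param component Component index or center window `c(lo, hi)` nm, passed
#'   to [state_population()] per fit/condition.
#' @return A [titration_series()]; direction auto-tagged from the trend.
#' @export
titrate_from_fits <- function(fits, component) {
  entries <- list()
  push <- function(fit, cond_i) {
    tr <- fit$conditions$traces[[cond_i]]
    pH <- tr$meta$pH
    if (is.null(pH))
      stop("condition '", rownames(fit$populations)[cond_i],
           "' carries no pH metadata", call. = FALSE)
    sp <- tryCatch(state_population(fit, component, cond_i),
                   error = function(e)
                     stop("component selection failed at pH ", pH, ": ",
                          conditionMessage(e), call. = FALSE))
    entries[[length(entries) + 1L]] <<- c(pH = pH, f = sp$population,
                                          sigma2 = sp$uncertainty)
  }
  if (inherits(fits, "deer_global_fit")) {
    pairs <- unique(unlist(lapply(fits$conditions$traces, function(t) t$meta$pair)))
    for (c in seq_len(nrow(fits$populations))) push(fits, c)
  } else {
    if (!length(fits) || !all(vapply(fits, inherits, logical(1), "deer_global_fit")))
      stop("`fits` must be a deer_global_fit or a list of them", call. = FALSE)
    pairs <- unique(unlist(lapply(fits, function(f)
      lapply(f$conditions$traces, function(t) t$meta$pair))))
    for (f in fits) for (c in seq_len(nrow(f$populations))) push(f, c)
  }
  if (length(pairs) > 1L)
    stop("fits mix spin-pair labels: ", paste(pairs, collapse = ", "), call. = FALSE)
  m <- do.call(rbind, entries)
  titration_series(m[, "pH"], m[, "f"], m[, "sigma2"])
}
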