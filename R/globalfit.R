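#' Bundle of DEER traces measured under different conditions
#'
#' Groups decays recorded on the same spin-labeled pair under different
#' conditions (pH values, micelle vs. nanodisc) for global analysis. Each
#' trace is one condition: Gaussian centers and widths are shared across the
#' set, while populations, background and modulation depth are free per
#' trace.
#'
#' @param traces List of [dipolar_trace()] objects (>= 1).
#' @param labels Optional condition identifiers; defaults to `meta$pH` or
#'   `meta$label` when present, else `"cond<i>"`.
#' @return Object of class `condition_set`.
#' @export
condition_set <- function(traces, labels = NULL) {
  if (is_dipolar_trace(traces)) traces <- list(traces)
  if (!length(traces) || !all(vapply(traces, is_dipolar_trace, logical(1))))
    stop("`traces` must be a non-empty list of dipolar_trace objects", call. = FALSE)
  pairs <- unique(unlist(lapply(traces, function(tr) tr$meta$pair)))
  if (length(pairs) > 1L)
    stop("all traces in a condition set must share the same pair label; got: ",
         paste(pairs, collapse = ", "), call. = FALSE)
  if (is.null(labels)) {
    labels <- vapply(seq_along(traces), function(i) {
      m <- traces[[i]]$meta
      if (!is.null(m$label)) as.character(m$label)
      else if (!is.null(m$pH)) paste0("pH", format(m$pH))
      else paste0("cond", i)
    }, character(1))
  }
  if (length(labels) != length(traces))
    stop("labels must match traces in length", call. = FALSE)
  if (anyDuplicated(labels)) labels <- make.unique(labels)
  structure(list(traces = traces, labels = labels), class = "condition_set")
}

is_condition_set <- function(x) inherits(x, "condition_set")

# ---- parameter bookkeeping ------------------------------------------------

# Layout: r0 (K), sigma (K), theta (C x (K-1), softmax populations),
# then per trace delta, kappa[, d].
par_index <- function(K, C, fit_dims) {
  idx <- list()
  pos <- 0L
  idx$r0 <- pos + seq_len(K); pos <- pos + K
  idx$sigma <- pos + seq_len(K); pos <- pos + K
  idx$theta <- if (K > 1L)
    matrix(pos + seq_len(C * (K - 1L)), nrow = C, byrow = TRUE) else
    matrix(integer(0), nrow = C, ncol = 0L)
  pos <- pos + C * (K - 1L)
  idx$delta <- pos + seq_len(C); pos <- pos + C
  idx$kappa <- pos + seq_len(C); pos <- pos + C
  if (fit_dims) { idx[["d"]] <- pos + seq_len(C); pos <- pos + C }
  idx$n <- pos
  idx
}

softmax_pop <- function(theta) {
  e <- exp(c(theta, 0) - max(c(theta, 0)))
  e / sum(e)
}

populations_from_par <- function(par, idx) {
  C <- length(idx$delta)
  K <- length(idx$r0)
  t(vapply(seq_len(C), function(c)
    if (K > 1L) softmax_pop(par[idx$theta[c, ]]) else 1,
    numeric(K)))
}

# Model V(t) for every trace; returns list of vectors.
model_traces <- function(par, idx, dat) {
  K <- length(idx$r0)
  r0 <- par[idx$r0]; sig <- par[idx$sigma]
  out <- vector("list", length(dat$traces))
  for (c in seq_along(dat$traces)) {
    a <- if (K > 1L) softmax_pop(par[idx$theta[c, ]]) else 1
    dens <- numeric(length(dat$r))
    for (k in seq_len(K))
      dens <- dens + a[k] * stats::dnorm(dat$r, r0[k], sig[k])
    mass <- sum(dat$wr * dens)
    S <- as.vector(dat$kernels[[c]] %*% (dat$wr * dens)) / mass
    d_c <- if (!is.null(idx[["d"]])) par[idx[["d"]][c]] else dat$d_fixed
    B <- exp(-par[idx$kappa[c]] * dat$traces[[c]]$t^(d_c / 3))
    delta <- par[idx$delta[c]]
    out[[c]] <- B * ((1 - delta) + delta * S)
  }
  out
}

residual_vector <- function(par, idx, dat) {
  mod <- model_traces(par, idx, dat)
  unlist(lapply(seq_along(mod), function(c)
    (mod[[c]] - dat$traces[[c]]$V) / dat$scale[c]), use.names = FALSE)
}

fit_bounds <- function(idx, grid) {
  lower <- numeric(idx$n); upper <- numeric(idx$n)
  lower[idx$r0] <- grid$r_min; upper[idx$r0] <- grid$r_max
  lower[idx$sigma] <- 0.05; upper[idx$sigma] <- 1.5
  if (length(idx$theta)) { lower[idx$theta] <- -15; upper[idx$theta] <- 15 }
  lower[idx$delta] <- 0.02; upper[idx$delta] <- 0.8
  lower[idx$kappa] <- 0; upper[idx$kappa] <- 25
  if (!is.null(idx[["d"]])) { lower[idx[["d"]]] <- 2; upper[idx[["d"]]] <- 3.5 }
  list(lower = lower, upper = upper)
}

# Multi-start schedule: one deterministic start with evenly spaced centers
# plus seeded jittered restarts; coarse screening, then refinement of the
# best candidates.
make_starts <- function(idx, grid, dat, n_starts, seed) {
  K <- length(idx$r0); C <- length(idx$delta)
  lo <- grid$r_min + 0.15 * (grid$r_max - grid$r_min)
  hi <- grid$r_max - 0.25 * (grid$r_max - grid$r_min)
  base <- numeric(idx$n)
  base[idx$sigma] <- 0.3
  base[idx$delta] <- 0.3
  base[idx$kappa] <- 0.2
  if (!is.null(idx[["d"]])) base[idx[["d"]]] <- 3
  # two deterministic center layouts: quantiles of the full grid and of the
  # 2.5-5.5 nm window where nitroxide-pair distances typically fall
  mk <- function(lo_, hi_) {
    s <- base
    s[idx$r0] <- if (K == 1L) (lo_ + hi_) / 2 else seq(lo_, hi_, length.out = K)
    s
  }
  starts <- list(mk(lo, hi),
                 mk(max(2.5, grid$r_min + 0.1), min(5.5, grid$r_max - 0.1)))
  base_centers <- starts[[1]][idx$r0]
  if (n_starts > 2L) {
    jit <- with_seed(seed, lapply(seq_len(n_starts - 2L), function(i)
      list(r0 = stats::rnorm(K, 0, 0.12 * (grid$r_max - grid$r_min)),
           sig = stats::runif(K, 0.1, 0.6),
           delta = stats::runif(1, 0.1, 0.6),
           kappa = stats::runif(1, 0.02, 0.8))))
    for (j in jit) {
      s <- base
      s[idx$r0] <- pmin(pmax(sort(base_centers + j$r0), grid$r_min + 0.05),
                        grid$r_max - 0.05)
      s[idx$sigma] <- j$sig
      s[idx$delta] <- j$delta
      s[idx$kappa] <- j$kappa
      starts <- c(starts, list(s))
    }
  }
  starts[seq_len(min(n_starts, length(starts)))]
}

# Warm start for a K+1 fit: split the widest component of a fitted K model.
expand_start <- function(fit) {
  idx_new <- par_index(fit$n_components + 1L, nrow(fit$populations),
                       fit$fit_dims)
  comps <- fit$components
  pops <- fit$populations
  k <- which.max(comps$sigma)
  new_r0 <- c(comps$r0[-k], comps$r0[k] - 0.7 * comps$sigma[k],
              comps$r0[k] + 0.7 * comps$sigma[k])
  new_sig <- c(comps$sigma[-k], rep(max(comps$sigma[k] / sqrt(2), 0.06), 2))
  ord <- order(new_r0)
  par <- numeric(idx_new$n)
  par[idx_new$r0] <- pmin(pmax(new_r0[ord], fit$grid$r_min + 0.05),
                          fit$grid$r_max - 0.05)
  par[idx_new$sigma] <- new_sig[ord]
  Kn <- fit$n_components + 1L
  for (c in seq_len(nrow(pops))) {
    a <- c(pops[c, -k], rep(pops[c, k] / 2, 2))[ord]
    a <- pmax(a, 1e-6); a <- a / sum(a)
    par[idx_new$theta[c, ]] <- log(a[-Kn] / a[Kn])
  }
  par[idx_new$delta] <- fit$per_trace$delta
  par[idx_new$kappa] <- fit$per_trace$kappa
  if (!is.null(idx_new[["d"]])) par[idx_new[["d"]]] <- fit$per_trace$d
  par
}

run_lm <- function(par0, idx, dat, bounds, maxiter) {
  minpack.lm::nls.lm(
    par = par0,
    lower = bounds$lower, upper = bounds$upper,
    fn = residual_vector, idx = idx, dat = dat,
    control = minpack.lm::nls.lm.control(maxiter = maxiter, nprint = 0))
}

# Canonical form: components sorted by center; softmax parameters remapped
# so reported populations are invariant to internal component ordering.
canonicalize_par <- function(par, idx) {
  K <- length(idx$r0)
  if (K == 1L) return(par)
  ord <- order(par[idx$r0])
  if (all(ord == seq_len(K))) return(par)
  out <- par
  out[idx$r0] <- par[idx$r0][ord]
  out[idx$sigma] <- par[idx$sigma][ord]
  for (c in seq_len(nrow(idx$theta))) {
    a <- softmax_pop(par[idx$theta[c, ]])[ord]
    a <- pmax(a, 1e-12)
    out[idx$theta[c, ]] <- log(a[-K] / a[K])
  }
  out
}

fit_core <- function(conditions, K, n_starts = 8, seed = 1, fit_dims = FALSE,
                     d = 3, grid = distance_grid(), starts = NULL,
                     extra_starts = NULL, maxiter = 200L) {
  traces <- conditions$traces
  C <- length(traces)
  idx <- par_index(K, C, fit_dims)
  dat <- list(traces = traces, r = grid$values, wr = trapz_weights(grid$values),
              kernels = lapply(traces, function(tr) dipolar_kernel(tr$t, grid)),
              scale = rep(1, C), d_fixed = d)
  bounds <- fit_bounds(idx, grid)
  if (is.null(starts)) starts <- make_starts(idx, grid, dat, n_starts, seed)
  starts <- c(starts, extra_starts)
  # coarse screening (iteration-capped: its non-convergence warnings are noise)
  screened <- suppressWarnings(lapply(starts, function(s)
    run_lm(s, idx, dat, bounds, maxiter = if (length(starts) > 1L) 30L else maxiter)))
  obj <- vapply(screened, function(f) f$deviance, numeric(1))
  keep <- order(obj)[seq_len(min(3L, length(screened)))]
  refined <- lapply(keep, function(i)
    run_lm(screened[[i]]$par, idx, dat, bounds, maxiter = maxiter))
  best <- refined[[which.min(vapply(refined, function(f) f$deviance, numeric(1)))]]
  if (!best$info %in% 1:4 && best$info != 0)
    warning("optimizer stopped without full convergence (info = ", best$info,
            "): returning best attempt", call. = FALSE)

  par <- canonicalize_par(best$par, idx)
  mod <- model_traces(par, idx, dat)
  n_c <- vapply(traces, function(tr) length(tr$t), numeric(1))
  rss <- vapply(seq_len(C), function(c) sum((mod[[c]] - traces[[c]]$V)^2), numeric(1))
  sigma_hat <- sqrt(rss / n_c)
  # weighted Jacobian at the solution for the parameter covariance
  dat_w <- dat
  dat_w$scale <- pmax(sigma_hat, 1e-8)
  Jw <- num_jacobian(function(p) residual_vector(p, idx, dat_w), par)
  JtJ <- crossprod(Jw)
  vcov <- tryCatch(solve(JtJ), error = function(e) NULL)
  singular <- is.null(vcov)
  if (singular)
    vcov <- tryCatch(solve(JtJ + diag(1e-8 * (diag(JtJ) + 1))),
                     error = function(e) matrix(NA_real_, idx$n, idx$n))

  pops <- populations_from_par(par, idx)
  pop_sd <- matrix(0, nrow = C, ncol = K)
  if (K > 1L && !anyNA(vcov)) {
    for (c in seq_len(C)) {
      th <- idx$theta[c, ]
      A <- num_jacobian(function(p) softmax_pop(p), par[th])
      pop_sd[c, ] <- sqrt(pmax(diag(A %*% vcov[th, th, drop = FALSE] %*% t(A)), 0))
    }
  }
  low_mod <- par[idx$delta] <= bounds$lower[idx$delta] + 1e-6
  if (any(low_mod))
    warning("modulation depth at lower bound for trace(s) ",
            paste(which(low_mod), collapse = ", "),
            ": distance information is weak (near-pure background)",
            call. = FALSE)

  comps <- data.frame(r0 = par[idx$r0], sigma = par[idx$sigma])
  per_trace <- data.frame(
    label = conditions$labels,
    delta = par[idx$delta], kappa = par[idx$kappa],
    d = if (fit_dims) par[idx[["d"]]] else rep(d, C),
    rss = rss, n = n_c, sigma_hat = sigma_hat,
    low_modulation = low_mod)
  rownames(pops) <- conditions$labels
  structure(list(
    n_components = K, components = comps,
    populations = pops, populations_2sigma = 2 * pop_sd,
    per_trace = per_trace, grid = grid, conditions = conditions,
    par = par, par_index = idx, vcov = vcov, vcov_singular = singular,
    objective = sum(rss), fit_dims = fit_dims, seed = seed,
    converged = best$info %in% 0:4), class = "deer_global_fit")
}

#' Fit a sum-of-Gaussians model to a single DEER trace
#'
#' Nonlinear least-squares fit of the full forward model (shared Gaussian
#' distance components, modulation depth and stretched-exponential
#' background) to one decay, with a seeded multi-start schedule.
#'
#' @param trace A [dipolar_trace()].
#' @param K Number of Gaussian components (>= 1).
#' @param grid Distance grid for P(r).
#' @param n_starts Number of multi-start initializations (first start is
#'   deterministic, the rest are seeded jitters).
#' @param seed Seed for the restart jitter.
#' @param fit_dims Fit the background dimensionality `d` per trace? When
#'   `FALSE` (default) `d` is fixed at `d_fixed`.
#' @param d_fixed Fixed background dimensionality.
#' @param starts Optional list of full start vectors (advanced use;
#'   overrides the multi-start schedule).
#' @return A `deer_global_fit` object (see [fit_global()]).
#' @export
fit_single <- function(trace, K, grid = distance_grid(), n_starts = 8,
                       seed = 1, fit_dims = FALSE, d_fixed = 3, starts = NULL) {
  if (K < 1) stop("K must be >= 1", call. = FALSE)
  fit_core(condition_set(list(trace)), K, n_starts = n_starts, seed = seed,
           fit_dims = fit_dims, d = d_fixed, grid = grid, starts = starts)
}

#' Global fit of DEER traces across conditions
#'
#' Fits all traces of a [condition_set()] simultaneously: Gaussian centers
#' and widths are shared across conditions (conformer geometry is
#' condition-independent), populations are free per condition, and
#' background and modulation depth are free per trace. The objective is the
#' sum of per-trace residual sums of squares.
#'
#' @inheritParams fit_single
#' @param conditions A [condition_set()].
#' @return Object of class `deer_global_fit` with elements `components`
#'   (shared centers/widths, sorted by center), `populations` (conditions x
#'   components, rows sum to 1), `populations_2sigma`, `per_trace`
#'   (delta, kappa, d, RSS, noise estimate), `vcov`, `objective`.
#' @export
fit_global <- function(conditions, K, grid = distance_grid(), n_starts = 8,
                       seed = 1, fit_dims = FALSE, d_fixed = 3, starts = NULL) {
  if (!is_condition_set(conditions)) conditions <- condition_set(conditions)
  if (K < 1) stop("K must be >= 1", call. = FALSE)
  fit_core(conditions, K, n_starts = n_starts, seed = seed,
           fit_dims = fit_dims, d = d_fixed, grid = grid, starts = starts)
}

#' @export
print.deer_global_fit <- function(x, ...) {
  cat(sprintf("<deer_global_fit> K = %d component(s), %d condition(s), RSS = %.4g\n",
              x$n_components, nrow(x$populations), x$objective))
  comp <- cbind(x$components, t(x$populations))
  print(round(comp, 4))
  invisible(x)
}

# Information criteria on the concatenated residuals, per-trace Gaussian
# noise variance estimated from the fit (ML).
fit_criterion <- function(fit, criterion = c("bic", "aicc")) {
  criterion <- match.arg(criterion)
  n_c <- fit$per_trace$n
  rss <- fit$per_trace$rss
  n <- sum(n_c)
  p <- fit$par_index$n
  ll_term <- sum(n_c * log(pmax(rss / n_c, 1e-300)))
  switch(criterion,
         bic = ll_term + p * log(n),
         aicc = ll_term + 2 * p + 2 * p * (p + 1) / max(n - p - 1, 1))
}

#' Select the number of Gaussian components by an information criterion
#'
#' Fits `K = 1..K_max` globally and returns the fit minimizing the
#' criterion (BIC by default, AICc as alternative); ties break toward the
#' smaller K. All candidate criterion values are retained in
#' `$criterion_table`.
#'
#' @inheritParams fit_global
#' @param K_max Largest candidate component count (default 4).
#' @param criterion `"bic"` (default) or `"aicc"`.
#' @return The selected `deer_global_fit`, with `criterion_table`
#'   (data.frame of K, criterion value, RSS, convergence) attached.
#' @export
choose_model <- function(conditions, K_max = 4, criterion = c("bic", "aicc"),
                         grid = distance_grid(), n_starts = 8, seed = 1,
                         fit_dims = FALSE, d_fixed = 3) {
  criterion <- match.arg(criterion)
  if (!is_condition_set(conditions)) conditions <- condition_set(conditions)
  if (K_max < 1) stop("K_max must be >= 1", call. = FALSE)
  fits <- vector("list", K_max)
  crit <- rep(NA_real_, K_max)
  errs <- character(0)
  for (K in seq_len(K_max)) {
    # warm start each K from the previous fit with its widest component split
    warm <- if (K > 1L && !is.null(fits[[K - 1L]]))
      list(expand_start(fits[[K - 1L]])) else NULL
    fits[[K]] <- tryCatch(
      fit_core(conditions, K, grid = grid, n_starts = n_starts,
               seed = derive_seed(seed, K), fit_dims = fit_dims,
               d = d_fixed, extra_starts = warm),
      error = function(e) { errs <<- c(errs, conditionMessage(e)); NULL })
    if (!is.null(fits[[K]])) crit[K] <- fit_criterion(fits[[K]], criterion)
  }
  if (all(is.na(crit)))
    stop("model selection failed for every candidate K: ",
         paste(unique(errs), collapse = "; "), call. = FALSE)
  best_K <- which.min(crit)   # which.min takes the first (smallest K) on ties
  out <- fits[[best_K]]
  out$criterion <- criterion
  out$criterion_table <- data.frame(
    K = seq_len(K_max), criterion = crit,
    rss = vapply(fits, function(f) if (is.null(f)) NA_real_ else f$objective,
                 numeric(1)),
    converged = vapply(fits, function(f) !is.null(f) && f$converged, logical(1)))
  out
}

# P(r) density for one condition as a function of the full parameter vector.
density_from_par <- function(par, idx, grid, cond) {
  K <- length(idx$r0)
  a <- if (K > 1L) softmax_pop(par[idx$theta[cond, ]]) else 1
  dens <- numeric(length(grid$values))
  for (k in seq_len(K))
    dens <- dens + a[k] * stats::dnorm(grid$values, par[idx$r0[k]], par[idx$sigma[k]])
  w <- trapz_weights(grid$values)
  dens / sum(w * dens)
}

#' Pointwise confidence band on fitted distance distributions
#'
#' Propagates the parameter covariance of a converged fit to a pointwise
#' envelope on P(r) for every condition, by first-order (delta-method)
#' propagation or by seeded parametric bootstrap. The lower bound is
#' clipped at zero.
#'
#' @param fit A `deer_global_fit`.
#' @param level Sigma multiple (default 2, i.e. ~95%).
#' @param method `"delta"` (default) or `"bootstrap"`.
#' @param include_background Include background/depth parameters in the
#'   propagated covariance? P(r) does not depend on them directly, so this
#'   matters only through refitting in the bootstrap.
#' @param n_boot Bootstrap replicates (method = "bootstrap").
#' @param seed Seed for the bootstrap noise.
#' @return Named list (one element per condition label) of data.frames with
#'   columns `r`, `fit`, `lower`, `upper`.
#' @export
confidence_band <- function(fit, level = 2, method = c("delta", "bootstrap"),
                            include_background = TRUE, n_boot = 200, seed = 1) {
  method <- match.arg(method)
  stopifnot(inherits(fit, "deer_global_fit"))
  idx <- fit$par_index
  C <- nrow(fit$populations)
  grid <- fit$grid
  if (method == "delta") {
    if (fit$vcov_singular || anyNA(fit$vcov))
      stop("parameter covariance is singular; use method = \"bootstrap\"",
           call. = FALSE)
    V <- fit$vcov
    if (!include_background) {
      drop_i <- c(idx$delta, idx$kappa, if (!is.null(idx[["d"]])) idx[["d"]])
      V[drop_i, ] <- 0; V[, drop_i] <- 0
    }
    out <- lapply(seq_len(C), function(c) {
      G <- num_jacobian(function(p) density_from_par(p, idx, grid, c), fit$par)
      sd_p <- sqrt(pmax(rowSums((G %*% V) * G), 0))
      p0 <- density_from_par(fit$par, idx, grid, c)
      data.frame(r = grid$values, fit = p0,
                 lower = pmax(p0 - level * sd_p, 0), upper = p0 + level * sd_p)
    })
  } else {
    mod <- model_traces(fit$par, idx, list(
      traces = fit$conditions$traces, r = grid$values,
      wr = trapz_weights(grid$values),
      kernels = lapply(fit$conditions$traces, function(tr) dipolar_kernel(tr$t, grid)),
      scale = rep(1, C), d_fixed = fit$per_trace$d[1]))
    sig <- fit$per_trace$sigma_hat
    dens_acc <- lapply(seq_len(C), function(c)
      matrix(NA_real_, nrow = n_boot, ncol = length(grid$values)))
    for (b in seq_len(n_boot)) {
      bseed <- derive_seed(seed, b)
      traces_b <- lapply(seq_len(C), function(c)
        add_noise(dipolar_trace(fit$conditions$traces[[c]]$t, mod[[c]],
                                fit$conditions$traces[[c]]$meta),
                  sig[c], derive_seed(bseed, c)))
      fb <- suppressWarnings(tryCatch(
        fit_core(condition_set(traces_b, fit$conditions$labels),
                 fit$n_components, grid = grid, starts = list(fit$par),
                 fit_dims = fit$fit_dims, d = fit$per_trace$d[1],
                 maxiter = 100L),
        error = function(e) NULL))
      if (is.null(fb)) next
      for (c in seq_len(C))
        dens_acc[[c]][b, ] <- density_from_par(fb$par, fb$par_index, grid, c)
    }
    out <- lapply(seq_len(C), function(c) {
      p0 <- density_from_par(fit$par, idx, grid, c)
      sd_p <- apply(dens_acc[[c]], 2, stats::sd, na.rm = TRUE)
      data.frame(r = grid$values, fit = p0,
                 lower = pmax(p0 - level * sd_p, 0), upper = p0 + level * sd_p)
    })
  }
  names(out) <- rownames(fit$populations)
  out
}

#' Population of a fitted state with uncertainty
#'
#' @param fit A `deer_global_fit`.
#' @param component Component index, or a length-2 numeric window
#'   `c(lo, hi)` in nm that must contain exactly one fitted center.
#' @param condition Condition label or index (default 1).
#' @param level Sigma multiple for the reported uncertainty (default 2).
#' @return List with `population`, `uncertainty` (level x sigma), `center`,
#'   `component` and `condition`.
#' @export
state_population <- function(fit, component, condition = 1, level = 2) {
  stopifnot(inherits(fit, "deer_global_fit"))
  K <- fit$n_components
  if (length(component) == 2L) {
    hits <- which(fit$components$r0 >= component[1] & fit$components$r0 <= component[2])
    if (length(hits) != 1L)
      stop(sprintf("center window [%g, %g] nm matches %d components (need exactly 1)",
                   component[1], component[2], length(hits)), call. = FALSE)
    component <- hits
  }
  if (!(component %in% seq_len(K)))
    stop("component index out of range", call. = FALSE)
  if (is.character(condition)) {
    ci <- match(condition, rownames(fit$populations))
    if (is.na(ci)) stop("unknown condition label: ", condition, call. = FALSE)
    condition <- ci
  }
  list(population = unname(fit$populations[condition, component]),
       uncertainty = unname(fit$populations_2sigma[condition, component] / 2 * level),
       center = fit$components$r0[component],
       component = component, condition = rownames(fit$populations)[condition])
}

#' Fitted distance distribution of one condition
#'
#' @param fit A `deer_global_fit`.
#' @param condition Condition label or index.
#' @return A [distance_distribution()] with the fitted components.
#' @export
fitted_distribution <- function(fit, condition = 1) {
  stopifnot(inherits(fit, "deer_global_fit"))
  if (is.character(condition))
    condition <- match(condition, rownames(fit$populations))
  comps <- gaussian_components(fit$components$r0, fit$components$sigma,
                               fit$populations[condition, ])
  distance_distribution(fit$grid, components = comps)
}
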