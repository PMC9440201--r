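# Parameter-recovery tests use the generator as the oracle throughout:
# the forward model that built the trace is the truth the fit must recover.

test_that("noiseless single-Gaussian trace is recovered to high precision", {
  tr <- reference_trace(r0 = 3.5, sigma = 0.25, delta = 0.3, kappa = 0.2)
  f <- fit_single(tr, 1, seed = 1)
  expect_lt(abs(f$components$r0 - 3.5), 1e-3)
  expect_lt(abs(f$components$sigma - 0.25), 1e-3)
  expect_lt(abs(f$per_trace$delta - 0.3), 1e-3)
  expect_lt(abs(f$per_trace$kappa - 0.2), 1e-3)
  expect_true(f$converged)
})

test_that("noisy single-Gaussian centers are recovered within 0.02 nm (median over seeds)", {
  tr <- reference_trace(r0 = 3.5, sigma = 0.25)
  errs <- vapply(1:50, function(s) {
    noisy <- add_noise(tr, 0.005, s)
    f <- suppressWarnings(fit_single(noisy, 1, n_starts = 4, seed = s))
    abs(f$components$r0 - 3.5)
  }, numeric(1))
  expect_lte(median(errs), 0.02)
})

test_that("near-pure background flags a low-modulation warning", {
  t <- seq(0, 3, length.out = 300)
  tr <- add_noise(dipolar_trace(t, deer_background(t, 0.3, 3)), 0.002, 5)
  expect_warning(fit_single(tr, 1, n_starts = 2, seed = 1), "modulation")
})

test_that("global fit on one condition reduces to the single-trace fit", {
  tr <- add_noise(reference_trace(), 0.005, 9)
  f1 <- fit_single(tr, 1, seed = 3)
  fg <- fit_global(condition_set(list(tr)), 1, seed = 3)
  expect_equal(fg$objective, f1$objective, tolerance = 1e-9)
  expect_equal(fg$components, f1$components, tolerance = 1e-9)
})

test_that("global two-condition fit recovers shared shapes and per-condition populations", {
  g <- distance_grid()
  t <- seq(0, 3, length.out = 300)
  mk <- function(a1, kappa, seed, pH) {
    comps <- gaussian_components(c(3.0, 4.5), c(0.3, 0.3), c(a1, 1 - a1))
    P <- distance_distribution(g, components = comps)
    add_noise(compose_signal(P, background_model(kappa), 0.3, t,
                             meta = list(pair = "p", pH = pH)),
              0.003, seed)  # SNR 100
  }
  cs <- condition_set(list(mk(0.8, 0.2, 21, 4), mk(0.3, 0.25, 22, 9)))
  fit <- fit_global(cs, 2, seed = 2)
  expect_equal(fit$components$r0, c(3.0, 4.5), tolerance = 0.03)
  expect_lt(max(abs(fit$populations[1, ] - c(0.8, 0.2))), 0.05)
  expect_lt(max(abs(fit$populations[2, ] - c(0.3, 0.7))), 0.05)
  # populations are normalized per condition
  expect_equal(unname(rowSums(fit$populations)), c(1, 1), tolerance = 1e-6)
  # permuting conditions leaves shared parameters unchanged
  fit_perm <- fit_global(condition_set(list(cs$traces[[2]], cs$traces[[1]])),
                         2, seed = 2)
  expect_equal(fit_perm$components$r0, fit$components$r0, tolerance = 1e-4)
  expect_equal(unname(fit_perm$populations[1, ]), unname(fit$populations[2, ]),
               tolerance = 1e-3)
  # duplicated traces give identical per-condition populations
  fit_dup <- fit_global(condition_set(list(cs$traces[[1]], cs$traces[[1]]),
                                      labels = c("a", "b")), 2, seed = 2)
  expect_lt(max(abs(fit_dup$populations[1, ] - fit_dup$populations[2, ])), 1e-6)
})

test_that("objective never increases with K (nested models)", {
  tr <- add_noise(reference_trace(), 0.006, 4)
  cs <- condition_set(list(tr))
  obj <- vapply(1:3, function(K)
    suppressWarnings(fit_global(cs, K, seed = K))$objective, numeric(1))
  # allow tiny optimizer slack on an effectively flat landscape
  expect_true(all(diff(obj) <= 1e-6))
})

test_that("model selection returns K_max = 1 unconditionally and keeps the criterion table", {
  tr <- add_noise(reference_trace(), 0.006, 11)
  m <- suppressWarnings(choose_model(condition_set(list(tr)), K_max = 1, seed = 1))
  expect_equal(m$n_components, 1)
  expect_equal(nrow(m$criterion_table), 1)
  m3 <- suppressWarnings(choose_model(condition_set(list(tr)), K_max = 3, seed = 1))
  expect_equal(nrow(m3$criterion_table), 3)
  expect_false(any(is.na(m3$criterion_table$criterion)))
})

test_that("state_population selects by index and by center window", {
  g <- distance_grid()
  t <- seq(0, 3, length.out = 300)
  comps <- gaussian_components(c(3.0, 4.5), c(0.3, 0.3), c(0.6, 0.4))
  P <- distance_distribution(g, components = comps)
  tr <- add_noise(compose_signal(P, background_model(0.2), 0.3, t), 0.003, 31)
  fit <- fit_global(condition_set(list(tr)), 2, seed = 5)
  sp <- state_population(fit, c(2.9, 3.1))
  expect_equal(sp$component, 1)
  expect_lt(abs(sp$population - 0.6), 0.05)
  expect_gt(sp$uncertainty, 0)
  both <- state_population(fit, 1)$population + state_population(fit, 2)$population
  expect_equal(both, 1, tolerance = 1e-6)
  expect_error(state_population(fit, c(1.5, 8)), "matches 2")
  expect_error(state_population(fit, c(2.0, 2.2)), "matches 0")
})

test_that("confidence bands are tight without noise and bracket the fit", {
  tr <- reference_trace()
  f <- fit_single(tr, 1, seed = 1)
  band <- confidence_band(f)[[1]]
  expect_true(all(band$upper >= band$fit & band$fit >= band$lower))
  expect_true(all(band$lower >= 0))
  expect_lt(max(band$upper - band$lower) / 2, 1e-4)
})

test_that("delta-method and bootstrap bands agree within a factor of two", {
  tr <- add_noise(reference_trace(), 0.01, 77)
  f <- suppressWarnings(fit_single(tr, 1, n_starts = 4, seed = 1))
  bd <- confidence_band(f, method = "delta")[[1]]
  bb <- confidence_band(f, method = "bootstrap", n_boot = 100, seed = 2)[[1]]
  sel <- bd$fit > 0.05 * max(bd$fit)
  ratio <- (bd$upper - bd$lower)[sel] / pmax((bb$upper - bb$lower)[sel], 1e-12)
  expect_gte(median(ratio), 0.5)
  expect_lte(median(ratio), 2)
})
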