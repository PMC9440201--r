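#' Specification of a pH-coupled two-state conformational equilibrium
#'
#' Defines the ground truth for synthetic DEER datasets: two conformational
#' states, each a sum of Gaussians, exchanging with pH according to a Hill
#' titration. The defaults emulate an intracellular distance pair of a
#' proton-coupled MFS transporter: a short-distance (closed) state that
#' dominates at acidic pH and a long-distance (open) state at basic pH,
#' populations shifting 0.8 -> 0.2 across pH 4 -> 9 with a midpoint at
#' pK 7.6 and Hill n = 1.
#'
#' @param state_A Gaussian components of the acid-favoured state.
#' @param state_B Gaussian components of the base-favoured state.
#' @param pK,n Hill midpoint and coefficient of the titration.
#' @param f_acid,f_base Plateau populations of state A at acidic / basic pH.
#' @param pH pH values of the dataset (>= 4).
#' @param delta Modulation depth per trace.
#' @param kappa,d Background rate and dimensionality.
#' @param environment `"micelle"` or `"nanodisc"`.
#' @param steep_acid_background Emulate the steeper nanodisc background at
#'   acidic pH (background rate scaled up by `steep_factor` below pH 4.5)?
#' @param steep_factor Multiplier on `kappa` for the acidic-pH traces.
#' @param noise_sigma Additive white-noise standard deviation; the default
#'   corresponds to SNR = delta / noise_sigma = 50.
#' @param t_max,n_points Trace length (us) and number of time points.
#' @param pair Spin-pair label carried in the metadata.
#' @param grid Distance grid.
#' @return Object of class `equilibrium_spec`.
#' @export
equilibrium_spec <- function(state_A = gaussian_components(3.0, 0.3),
                             state_B = gaussian_components(4.5, 0.3),
                             pK = 7.6, n = 1, f_acid = 0.8, f_base = 0.2,
                             pH = c(4, 5, 6, 7, 7.5, 8, 9),
                             delta = 0.3, kappa = 0.2, d = 3,
                             environment = "micelle",
                             steep_acid_background = FALSE, steep_factor = 3,
                             noise_sigma = 0.006, t_max = 3, n_points = 300,
                             pair = "site1-site2", grid = distance_grid()) {
  if (length(unique(pH)) < 4L) stop("need >= 4 pH values", call. = FALSE)
  stopifnot_scalar(pK, "pK"); stopifnot_scalar(n, "n", lower = 1e-3)
  stopifnot_scalar(f_acid, "f_acid", lower = 0, upper = 1)
  stopifnot_scalar(f_base, "f_base", lower = 0, upper = 1)
  stopifnot_scalar(noise_sigma, "noise_sigma", lower = 0)
  if (!environment %in% c("micelle", "nanodisc"))
    stop("environment must be 'micelle' or 'nanodisc'", call. = FALSE)
  structure(list(state_A = state_A, state_B = state_B, pK = pK, n = n,
                 f_acid = f_acid, f_base = f_base, pH = sort(pH),
                 delta = delta, kappa = kappa, d = d,
                 environment = environment,
                 steep_acid_background = steep_acid_background,
                 steep_factor = steep_factor,
                 noise_sigma = noise_sigma, t_max = t_max,
                 n_points = n_points, pair = pair, grid = grid),
            class = "equilibrium_spec")
}

#' Generate a pH series of two-state DEER traces with known truth
#'
#' For each pH, the distance distribution is the Hill-weighted mixture
#' `f(pH) * P_A + (1 - f(pH)) * P_B`; traces are composed with the forward
#' model and white noise is added with per-condition sub-seeds derived
#' deterministically from `seed`.
#'
#' @param spec An [equilibrium_spec()].
#' @param seed Integer seed fixing all randomness.
#' @return List with `conditions` (a [condition_set()]) and `truth` (the
#'   spec parameters plus the per-pH mixture weights and backgrounds).
#' @export
generate_deer_dataset <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "equilibrium_spec"))
  t <- seq(0, spec$t_max, length.out = spec$n_points)
  f <- hill_curve(spec$pH, spec$pK, spec$n, spec$f_acid, spec$f_base)
  kappa_pH <- rep(spec$kappa, length(spec$pH))
  if (spec$steep_acid_background && spec$environment == "nanodisc")
    kappa_pH[spec$pH <= 4.5] <- spec$kappa * spec$steep_factor
  traces <- vector("list", length(spec$pH))
  for (i in seq_along(spec$pH)) {
    comps <- gaussian_components(
      c(spec$state_A$r0, spec$state_B$r0),
      c(spec$state_A$sigma, spec$state_B$sigma),
      c(f[i] * spec$state_A$a, (1 - f[i]) * spec$state_B$a))
    P <- distance_distribution(spec$grid, components = comps)
    tr <- compose_signal(P, background_model(kappa_pH[i], spec$d), spec$delta,
                         t, meta = list(pair = spec$pair, pH = spec$pH[i],
                                        environment = spec$environment))
    traces[[i]] <- add_noise(tr, spec$noise_sigma, derive_seed(seed, i))
  }
  truth <- list(pK = spec$pK, n = spec$n, f_acid = spec$f_acid,
                f_base = spec$f_base, pH = spec$pH, f_state_A = f,
                centers = c(spec$state_A$r0, spec$state_B$r0),
                widths = c(spec$state_A$sigma, spec$state_B$sigma),
                state_A = spec$state_A, state_B = spec$state_B,
                delta = spec$delta, kappa = kappa_pH, d = spec$d,
                noise_sigma = spec$noise_sigma, seed = seed,
                environment = spec$environment, pair = spec$pair)
  list(conditions = condition_set(traces), truth = truth)
}

#' Generate a noisy titration table with known truth
#'
#' @param pK,n,f_acid,f_base Hill parameters of the generating curve.
#' @param pH pH values.
#' @param noise_sigma Gaussian noise on the populations (clipped to [0, 1]).
#' @param seed Integer seed.
#' @return List with `series` (a [titration_series()], `sigma2` set to
#'   `2 * noise_sigma`) and `truth`.
#' @export
generate_titration_table <- function(pK = 7.6, n = 1, f_acid = 0.8,
                                     f_base = 0.2,
                                     pH = seq(4, 9, length.out = 9),
                                     noise_sigma = 0, seed = 1) {
  f0 <- hill_curve(pH, pK, n, f_acid, f_base)
  f <- if (noise_sigma > 0)
    pmin(pmax(f0 + with_seed(seed, stats::rnorm(length(pH), sd = noise_sigma)), 0), 1)
  else f0
  series <- titration_series(pH, f, sigma2 = rep(2 * noise_sigma, length(pH)))
  list(series = series,
       truth = list(pK = pK, n = n, f_acid = f_acid, f_base = f_base,
                    pH = pH, f_clean = f0, noise_sigma = noise_sigma,
                    seed = seed))
}

# Backbone of one ideal poly-Ala helix along +z; returns an atom table.
build_helix <- function(n_res, origin, chain, resno_start, phase = 0,
                        helix_radius = 2.3, rise = 1.5, twist = 100) {
  rows <- list()
  axis_dir <- c(0, 0, 1)
  for (i in seq_len(n_res)) {
    ang <- (phase + (i - 1) * twist) * pi / 180
    ca <- origin + helix_radius * c(cos(ang), sin(ang), 0) + (i - 1) * rise * axis_dir
    ang_prev <- (phase + (i - 2) * twist) * pi / 180
    ca_prev <- origin + helix_radius * c(cos(ang_prev), sin(ang_prev), 0) +
      (i - 2) * rise * axis_dir
    u <- ca_prev - ca
    u <- u / sqrt(sum(u^2))
    n_at <- ca + 1.46 * u
    radial <- c(cos(ang), sin(ang), 0)
    cb <- ca + 1.53 * (radial * 0.94 + c(0, 0, -0.34))
    resno <- resno_start + i - 1
    rows[[i]] <- data.frame(
      elety = c("N", "CA", "CB"), resid = "ALA", chain = chain,
      resno = resno, elesy = c("N", "C", "C"),
      x = c(n_at[1], ca[1], cb[1]), y = c(n_at[2], ca[2], cb[2]),
      z = c(n_at[3], ca[3], cb[3]))
  }
  do.call(rbind, rows)
}

#' Generate a toy multi-helix bundle structure
#'
#' Ideal poly-alanine helices (1.5 A rise, 100 deg twist) arranged on a
#' circle, standing in for a transmembrane helix bundle. Every residue has
#' N, CA and CB atoms so any site can be labelled. Deterministic given the
#' seed (randomness enters only through the optional coordinate jitter).
#'
#' @param n_helices Number of helices (>= 2).
#' @param n_res Residues per helix.
#' @param bundle_radius Circle radius the helix axes sit on, Angstrom.
#' @param jitter Gaussian coordinate jitter, Angstrom (default 0).
#' @param seed Seed (used only when `jitter > 0`).
#' @param path Optional path; when given, the structure is also written as
#'   a PDB file.
#' @return A `structure_model` (single model).
#' @export
generate_toy_bundle <- function(n_helices = 12, n_res = 20, bundle_radius = 25,
                                jitter = 0, seed = 1, path = NULL) {
  if (n_helices < 2) stop("need at least 2 helices", call. = FALSE)
  tabs <- lapply(seq_len(n_helices), function(h) {
    ang <- 2 * pi * (h - 1) / n_helices
    origin <- bundle_radius * c(cos(ang), sin(ang), 0)
    build_helix(n_res, origin, chain = "A",
                resno_start = (h - 1) * n_res + 1, phase = h * 40)
  })
  atoms <- do.call(rbind, tabs)
  xyz <- matrix(as.vector(t(as.matrix(atoms[, c("x", "y", "z")]))), nrow = 1)
  if (jitter > 0)
    xyz <- xyz + with_seed(seed, stats::rnorm(length(xyz), sd = jitter))
  st <- structure_model(atoms, xyz)
  if (!is.null(path)) write_structure(st, path)
  st
}

#' Generate a salt-bridge breaking trajectory with known schedule
#'
#' Minimal Arg/Asp two-residue system whose minimum side-chain N-O distance
#' follows a step schedule: `formed` Angstrom for frames up to
#' `switch_frame`, `broken` afterwards, plus optional per-frame jitter.
#'
#' @param n_frames Number of frames.
#' @param formed,broken Minimum N-O distance in the two regimes, Angstrom.
#' @param switch_frame Last frame of the formed regime (0..n_frames).
#' @param jitter Gaussian jitter on the scheduled distance, Angstrom.
#' @param seed Integer seed.
#' @param path Optional multi-model PDB output path.
#' @return List with `trajectory` (multi-model `structure_model`), `truth`
#'   (the schedule) and `pair` (a ready-made [salt_bridge_pair()]).
#' @export
generate_saltbridge_trajectory <- function(n_frames = 100, formed = 3.0,
                                           broken = 8.0,
                                           switch_frame = floor(n_frames / 2),
                                           jitter = 0, seed = 1, path = NULL) {
  if (n_frames < 1) stop("n_frames must be >= 1", call. = FALSE)
  if (switch_frame < 0 || switch_frame > n_frames)
    stop("switch_frame must lie in [0, n_frames]", call. = FALSE)
  sched <- ifelse(seq_len(n_frames) <= switch_frame, formed, broken)
  d_actual <- sched + if (jitter > 0)
    with_seed(seed, stats::rnorm(n_frames, sd = jitter)) else 0
  d_actual <- pmax(d_actual, 0.5)
  # ARG donor: NH1 at origin, other N atoms displaced away from the acceptor;
  # ASP acceptor: OD1 at (d, 0, 0), OD2 slightly farther.
  atoms <- data.frame(
    elety = c("CA", "NE", "NH1", "NH2", "CA", "OD1", "OD2"),
    resid = c(rep("ARG", 4), rep("ASP", 3)),
    chain = "A",
    resno = c(rep(42L, 4), rep(129L, 3)),
    elesy = c("C", "N", "N", "N", "C", "O", "O"),
    x = 0, y = 0, z = 0)
  base <- rbind(c(-3, 0, 0),      # ARG CA
                c(-1, 1.5, 0),    # NE
                c(0, 0, 0),       # NH1 (closest donor)
                c(-1, -1.5, 0),   # NH2
                c(5, 3, 0),       # ASP CA placeholder (shifted with OD1)
                c(0, 0, 0),       # OD1 (closest acceptor), x set per frame
                c(1.2, 0.8, 0))   # OD2
  xyz <- matrix(NA_real_, nrow = n_frames, ncol = 3 * nrow(atoms))
  for (f in seq_len(n_frames)) {
    fr <- base
    shift <- c(d_actual[f], 0, 0)
    fr[5, ] <- fr[5, ] + shift
    fr[6, ] <- fr[6, ] + shift
    fr[7, ] <- fr[7, ] + shift
    xyz[f, ] <- as.vector(t(fr))
  }
  traj <- structure_model(atoms, xyz)
  if (!is.null(path)) write_structure(traj, path)
  list(trajectory = traj,
       truth = list(schedule = sched, distances = d_actual,
                    switch_frame = switch_frame, formed = formed,
                    broken = broken, jitter = jitter, seed = seed),
       pair = salt_bridge_pair(donor = list(chain = "A", resno = 42L),
                               acceptor = list(chain = "A", resno = 129L)))
}
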