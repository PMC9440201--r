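#' Read a protein structure (single- or multi-model PDB)
#'
#' Thin wrapper around [bio3d::read.pdb()] that honours MODEL/ENDMDL
#' records, keeps the highest-occupancy alternate location per atom, and
#' preserves author residue numbering.
#'
#' @param path Path to a PDB file.
#' @return Object of class `structure_model`: `atoms` (data.frame with
#'   chain, resno, resid, elety, elesy, x, y, z of model 1), `xyz` (matrix,
#'   one row per model, 3N columns) and `n_models`.
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  atoms <- pdb$atom
  keep <- rep(TRUE, nrow(atoms))
  alt <- atoms$alt
  alt[is.na(alt)] <- ""
  if (any(alt != "")) {
    key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety, sep = "|")
    occ <- atoms$o
    occ[is.na(occ)] <- 1
    for (k in unique(key[duplicated(key)])) {
      i <- which(key == k)
      keep[i] <- FALSE
      keep[i[which.max(occ[i])]] <- TRUE
    }
  }
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  cols <- as.vector(t(outer(which(keep), c(2, 1, 0), function(i, o) 3 * i - o)))
  structure_model(atoms[keep, , drop = FALSE], xyz[, cols, drop = FALSE])
}

structure_model <- function(atoms, xyz) {
  atoms <- as.data.frame(atoms)
  if (!all(c("chain", "resno", "resid", "elety", "x", "y", "z") %in% names(atoms)))
    stop("atom table missing required columns", call. = FALSE)
  if (any(!is.finite(xyz))) stop("coordinates must be finite", call. = FALSE)
  if (ncol(xyz) != 3 * nrow(atoms))
    stop("xyz width must be 3 x atom count", call. = FALSE)
  rownames(atoms) <- NULL
  atoms$x <- xyz[1, seq(1, ncol(xyz), 3)]
  atoms$y <- xyz[1, seq(2, ncol(xyz), 3)]
  atoms$z <- xyz[1, seq(3, ncol(xyz), 3)]
  if (is.null(atoms$elesy) || all(is.na(atoms$elesy)) || all(atoms$elesy == ""))
    atoms$elesy <- substr(trimws(atoms$elety), 1, 1)
  structure(list(atoms = atoms, xyz = xyz, n_models = nrow(xyz)),
            class = "structure_model")
}

is_structure_model <- function(x) inherits(x, "structure_model")

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> %d atom(s), %d residue(s), %d model(s)\n",
              nrow(x$atoms), length(unique(paste(x$atoms$chain, x$atoms$resno))),
              x$n_models))
  invisible(x)
}

# Coordinates of one model as an N x 3 matrix.
model_coords <- function(structure, model = 1) {
  if (model < 1 || model > structure$n_models)
    stop("model index out of range", call. = FALSE)
  matrix(structure$xyz[model, ], ncol = 3, byrow = TRUE)
}

atom_coord <- function(structure, chain, resno, elety, model = 1) {
  i <- which(structure$atoms$chain == chain & structure$atoms$resno == resno &
               trimws(structure$atoms$elety) == elety)
  if (length(i) != 1L) return(NULL)
  model_coords(structure, model)[i, ]
}

#' Spin-label attachment site
#'
#' Resolves the N/CA/CB attachment frame of a labelling site. Glycine (no
#' CB) is rejected, as are sites whose frame atoms are missing.
#'
#' @param structure A `structure_model`.
#' @param chain Chain identifier.
#' @param resno Author residue number.
#' @param model Model index for the frame coordinates.
#' @return Object of class `label_site` with `N`, `CA`, `CB` coordinates (A).
#' @export
label_site <- function(structure, chain, resno, model = 1) {
  stopifnot(is_structure_model(structure))
  res <- structure$atoms[structure$atoms$chain == chain &
                           structure$atoms$resno == resno, , drop = FALSE]
  if (!nrow(res))
    stop(sprintf("no residue %s:%s in structure", chain, resno), call. = FALSE)
  if (any(res$resid == "GLY"))
    stop(sprintf("site %s:%s is glycine (no CB); cannot attach a label",
                 chain, resno), call. = FALSE)
  frame <- lapply(c("N", "CA", "CB"), function(a)
    atom_coord(structure, chain, resno, a, model))
  missing <- c("N", "CA", "CB")[vapply(frame, is.null, logical(1))]
  if (length(missing))
    stop(sprintf("site %s:%s lacks frame atom(s): %s", chain, resno,
                 paste(missing, collapse = ", ")), call. = FALSE)
  names(frame) <- c("N", "CA", "CB")
  d <- sqrt(sum((frame$CA - frame$CB)^2))
  if (d < 1.2 || d > 1.8)
    stop(sprintf("site %s:%s CA-CB distance %.2f A outside [1.2, 1.8]",
                 chain, resno, d), call. = FALSE)
  structure(c(frame, list(chain = chain, resno = resno)), class = "label_site")
}

parse_site <- function(structure, site, model = 1) {
  if (inherits(site, "label_site")) return(site)
  if (is.character(site) && length(site) == 1L) {
    parts <- strsplit(site, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2L)
      stop("site string must be 'chain:resnum', got '", site, "'", call. = FALSE)
    return(label_site(structure, parts[1], as.integer(parts[2]), model))
  }
  stop("site must be a label_site or a 'chain:resnum' string", call. = FALSE)
}

# Uniform directions within a cone of half-angle `half_angle` about axis u.
# The azimuthal reference `ref` is taken from the residue's own frame so the
# sampled cloud is rigid-motion equivariant.
sample_cone <- function(n, u, half_angle, ref = NULL) {
  cth <- stats::runif(n, cos(half_angle), 1)
  sth <- sqrt(pmax(1 - cth^2, 0))
  phi <- stats::runif(n, 0, 2 * pi)
  # orthonormal basis around u
  u <- u / sqrt(sum(u^2))
  if (is.null(ref) || sum((ref - sum(ref * u) * u)^2) < 1e-12)
    ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  cbind(sth * cos(phi), sth * sin(phi), cth) %*% rbind(e1, e2, u)
}

#' Accessible-volume cloud of spin-label positions
#'
#' Simplified stand-in for a rotamer-library calculation: candidate
#' unpaired-electron positions are drawn at a fixed tether length from CB,
#' uniformly within a cone about the CA->CB axis, and candidates that clash
#' with any heavy atom outside the labelled residue are rejected. Surviving
#' positions carry uniform weights; multi-model structures pool per-model
#' clouds with equal model weights.
#'
#' @param structure A `structure_model`.
#' @param site A `label_site` or `"chain:resnum"` string.
#' @param L Tether length from CB, Angstrom.
#' @param cone_half_angle Cone half-angle about the CA->CB axis, degrees.
#' @param n_samples Candidate positions per model.
#' @param clash_cutoff Minimum allowed distance to any heavy atom outside
#'   the labelled residue, Angstrom.
#' @param seed Seed; the same seed reproduces the cloud exactly.
#' @param models Model indices to use (default: all).
#' @return Object of class `label_cloud`: `positions` (survivors, A),
#'   `weights` (sum to 1), `candidates`, `kept` (logical), `site`,
#'   `survivor_fraction`.
#' @export
build_label_cloud <- function(structure, site, L = 7.0, cone_half_angle = 90,
                              n_samples = 2000, clash_cutoff = 2.5, seed = 1,
                              models = NULL) {
  stopifnot(is_structure_model(structure))
  stopifnot_scalar(L, "L", lower = 0.5, upper = 20)
  stopifnot_scalar(cone_half_angle, "cone_half_angle", lower = 1, upper = 180)
  stopifnot_scalar(clash_cutoff, "clash_cutoff", lower = 0, upper = 10)
  if (n_samples < 1) stop("n_samples must be >= 1", call. = FALSE)
  models <- models %||% seq_len(structure$n_models)
  heavy <- trimws(structure$atoms$elesy) != "H"
  site0 <- parse_site(structure, site, model = models[1])
  own <- structure$atoms$chain == site0$chain & structure$atoms$resno == site0$resno
  env_idx <- which(heavy & !own)

  all_pos <- list(); all_cand <- list(); all_kept <- list(); all_w <- list()
  dirs_by_model <- with_seed(seed, lapply(models, function(m) {
    st <- parse_site(structure, site, model = m)
    sample_cone(n_samples, st$CB - st$CA, cone_half_angle * pi / 180,
                ref = st$N - st$CA)
  }))
  for (mi in seq_along(models)) {
    m <- models[mi]
    st <- parse_site(structure, site, model = m)
    cand <- matrix(rep(st$CB, each = n_samples), ncol = 3) + L * dirs_by_model[[mi]]
    env <- model_coords(structure, m)[env_idx, , drop = FALSE]
    if (nrow(env)) {
      d2min <- vapply(seq_len(n_samples), function(i) {
        dx <- env[, 1] - cand[i, 1]; dy <- env[, 2] - cand[i, 2]
        dz <- env[, 3] - cand[i, 3]
        min(dx * dx + dy * dy + dz * dz)
      }, numeric(1))
      kept <- d2min >= clash_cutoff^2
    } else kept <- rep(TRUE, n_samples)
    all_cand[[mi]] <- cand
    all_kept[[mi]] <- kept
    if (any(kept)) {
      all_pos[[mi]] <- cand[kept, , drop = FALSE]
      all_w[[mi]] <- rep(1 / (length(models) * sum(kept)), sum(kept))
    }
  }
  pos <- do.call(rbind, all_pos)
  if (is.null(pos) || !nrow(pos))
    stop(sprintf("site %s:%s is buried: every candidate position clashes",
                 site0$chain, site0$resno), call. = FALSE)
  w <- unlist(all_w)
  structure(list(positions = pos, weights = w / sum(w),
                 candidates = do.call(rbind, all_cand),
                 kept = unlist(all_kept), site = site0,
                 survivor_fraction = mean(unlist(all_kept))),
            class = "label_cloud")
}

is_label_cloud <- function(x) inherits(x, "label_cloud")

#' @export
print.label_cloud <- function(x, ...) {
  cat(sprintf("<label_cloud> site %s:%s, %d survivor(s) of %d candidates (%.0f%%)\n",
              x$site$chain, x$site$resno, nrow(x$positions),
              length(x$kept), 100 * x$survivor_fraction))
  invisible(x)
}

#' Predicted inter-label distance distribution
#'
#' Weighted kernel-smoothed histogram of all pairwise distances between two
#' label clouds, reported in nm on a [distance_grid()].
#'
#' @param cloud1,cloud2 [build_label_cloud()] results (positions in A).
#' @param grid Distance grid (nm); must cover the observed distances.
#' @param smoothing Gaussian smoothing width, nm.
#' @return A [distance_distribution()] (trapezoidal integral 1).
#' @export
predict_distribution <- function(cloud1, cloud2, grid = distance_grid(),
                                 smoothing = 0.05) {
  if (!is_label_cloud(cloud1) || !is_label_cloud(cloud2))
    stop("inputs must be label_cloud objects", call. = FALSE)
  stopifnot_scalar(smoothing, "smoothing", lower = 1e-6)
  p1 <- cloud1$positions; p2 <- cloud2$positions
  # pairwise distances in nm (PDB coordinates are Angstrom)
  d2 <- outer(rowSums(p1^2), rowSums(p2^2), "+") - 2 * p1 %*% t(p2)
  d_nm <- 0.1 * sqrt(pmax(d2, 0))
  w <- outer(cloud1$weights, cloud2$weights)
  rng <- range(d_nm)
  if (rng[1] < grid$r_min || rng[2] > grid$r_max)
    stop(sprintf("grid [%g, %g] nm does not cover observed distances [%.3f, %.3f] nm",
                 grid$r_min, grid$r_max, rng[1], rng[2]), call. = FALSE)
  # weighted histogram on the grid (linear binning: each distance splits its
  # weight between the two flanking grid points, removing binning bias),
  # then Gaussian smoothing
  r <- grid$values
  dv <- pmin(pmax(as.vector(d_nm), r[1]), r[length(r)])
  wv <- as.vector(w)
  i_lo <- pmin(findInterval(dv, r), length(r) - 1L)
  frac <- (dv - r[i_lo]) / (r[i_lo + 1L] - r[i_lo])
  hist_w <- numeric(length(r))
  acc_lo <- tapply(wv * (1 - frac), i_lo, sum)
  acc_hi <- tapply(wv * frac, i_lo + 1L, sum)
  hist_w[as.integer(names(acc_lo))] <- acc_lo
  hist_w[as.integer(names(acc_hi))] <-
    hist_w[as.integer(names(acc_hi))] + acc_hi
  G <- stats::dnorm(outer(r, r, "-"), sd = smoothing)
  dens <- as.vector(G %*% hist_w)
  distance_distribution(grid, density = dens)
}
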