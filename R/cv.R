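# Standard atomic masses for center-of-mass computations.
atom_mass <- function(elesy) {
  m <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974)
  out <- m[trimws(elesy)]
  out[is.na(out)] <- 12.011
  unname(out)
}

#' Split transporter domains into intracellular/extracellular halves
#'
#' Splits the N- and C-domain residue ranges into two segments each,
#' either at the sequence midpoint ("two equal segments", the extra residue
#' of an odd count going to the first half) or at the median CA
#' z-coordinate with the membrane normal along +z (lower z =
#' intracellular).
#'
#' @param structure A `structure_model`.
#' @param N_range,C_range Residue numbers of the N- and C-domain
#'   (nonoverlapping integer vectors).
#' @param mode `"by-sequence"` (default) or `"by-z"`.
#' @param chain Chain identifier (default: first chain).
#' @param first_half `"intracellular"` or `"extracellular"`: which half of
#'   the sequence order the first segment represents (by-sequence mode).
#' @param model Model used for CA coordinates in by-z mode.
#' @return Object of class `domain_split` with residue sets `N_intra`,
#'   `N_extra`, `C_intra`, `C_extra`.
#' @export
split_domains <- function(structure, N_range, C_range,
                          mode = c("by-sequence", "by-z"),
                          chain = NULL, first_half = "intracellular",
                          model = 1) {
  mode <- match.arg(mode)
  stopifnot(is_structure_model(structure))
  if (length(intersect(N_range, C_range)))
    stop("N_range and C_range overlap", call. = FALSE)
  chain <- chain %||% structure$atoms$chain[1]
  present <- unique(structure$atoms$resno[structure$atoms$chain == chain])
  split_one <- function(rng, dom) {
    rng <- sort(unique(rng))
    missing <- setdiff(rng, present)
    if (length(missing))
      stop(dom, "-domain residues absent from structure: ",
           paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
    if (length(rng) < 2L) stop(dom, "-domain has fewer than 2 residues", call. = FALSE)
    if (mode == "by-sequence") {
      n1 <- ceiling(length(rng) / 2)     # odd counts: extra residue to first half
      first <- rng[seq_len(n1)]
      second <- rng[-seq_len(n1)]
      if (first_half == "intracellular") list(intra = first, extra = second)
      else list(intra = second, extra = first)
    } else {
      ca <- structure$atoms$chain == chain & structure$atoms$resno %in% rng &
        trimws(structure$atoms$elety) == "CA"
      if (!any(ca)) stop(dom, "-domain has no CA atoms", call. = FALSE)
      z <- model_coords(structure, model)[ca, 3]
      resno_ca <- structure$atoms$resno[ca]
      med <- stats::median(z)
      lower <- resno_ca[z < med]
      upper <- resno_ca[z >= med]
      if (!length(lower) || !length(upper))
        stop(dom, "-domain z-split produced an empty half", call. = FALSE)
      list(intra = lower, extra = upper)
    }
  }
  Nsp <- split_one(N_range, "N")
  Csp <- split_one(C_range, "C")
  structure(list(N_intra = Nsp$intra, N_extra = Nsp$extra,
                 C_intra = Csp$intra, C_extra = Csp$extra,
                 chain = chain, mode = mode), class = "domain_split")
}

center_of_mass <- function(structure, resnos, chain, model = 1,
                           mass_weighted = TRUE, ca_only = FALSE) {
  sel <- structure$atoms$chain == chain & structure$atoms$resno %in% resnos
  if (ca_only) sel <- sel & trimws(structure$atoms$elety) == "CA"
  if (!any(sel)) stop("empty atom selection for center of mass", call. = FALSE)
  xyz <- model_coords(structure, model)[sel, , drop = FALSE]
  w <- if (mass_weighted) atom_mass(structure$atoms$elesy[sel]) else
    rep(1, sum(sel))
  colSums(xyz * w) / sum(w)
}

angle_deg <- function(p1, vertex, p3) {
  v1 <- p1 - vertex
  v2 <- p3 - vertex
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 < 1e-9 || n2 < 1e-9)
    stop("degenerate geometry: zero-length vector at the angle vertex",
         call. = FALSE)
  acos(min(max(sum(v1 * v2) / (n1 * n2), -1), 1)) * 180 / pi
}

#' Orientation collective variables alpha and beta
#'
#' Inter-domain opening angles of an alternating-access transporter.
#' `alpha` (intracellular opening) is the angle at the center of mass of
#' the extracellular half of the whole protein, between the centers of mass
#' of the intracellular halves of the N- and C-domains; `beta` is the
#' symmetric extracellular angle (vertex at the intracellular half of the
#' protein, endpoints at the extracellular domain halves).
#'
#' @param structure A `structure_model` (one frame selected via `model`).
#' @param split A [split_domains()] result.
#' @param model Frame index.
#' @param mass_weighted Mass-weighted centers (default) or geometric.
#' @param ca_only Use CA atoms only instead of all atoms.
#' @return Named vector `c(alpha = ..., beta = ...)` in degrees, each in
#'   (0, 180].
#' @export
compute_alpha_beta <- function(structure, split, model = 1,
                               mass_weighted = TRUE, ca_only = FALSE) {
  stopifnot(is_structure_model(structure), inherits(split, "domain_split"))
  com <- function(res) center_of_mass(structure, res, split$chain, model,
                                      mass_weighted, ca_only)
  alpha <- angle_deg(com(split$N_intra),
                     com(c(split$N_extra, split$C_extra)),
                     com(split$C_intra))
  beta <- angle_deg(com(split$N_extra),
                    com(c(split$N_intra, split$C_intra)),
                    com(split$C_extra))
  c(alpha = alpha, beta = beta)
}

#' Salt-bridge pair definition
#'
#' @param donor List with `chain`, `resno` of the Arg/Lys donor.
#' @param acceptor List with `chain`, `resno` of the Asp/Glu acceptor.
#' @param cutoff Formed-state cutoff on the minimum side-chain N-O
#'   distance, Angstrom (conventionally 4).
#' @return Object of class `salt_bridge_pair`.
#' @export
salt_bridge_pair <- function(donor, acceptor, cutoff = 4.0) {
  stopifnot_scalar(cutoff, "cutoff", lower = 1e-9)
  structure(list(donor = donor, acceptor = acceptor, cutoff = cutoff,
                 donor_atoms = c("NE", "NH1", "NH2", "NZ"),
                 acceptor_atoms = c("OD1", "OD2", "OE1", "OE2")),
            class = "salt_bridge_pair")
}

#' Salt-bridge distance time series with moving average
#'
#' Per frame, the minimum distance over all donor side-chain nitrogens
#' (NE/NH1/NH2/NZ) x acceptor carboxylate oxygens (OD1/OD2/OE1/OE2), with a
#' centered moving average (edge-truncated window) and the fraction of
#' frames below the formed cutoff. Frames missing the side-chain atoms are
#' recorded as errors and excluded from averages and the formed fraction.
#'
#' @param trajectory A multi-model `structure_model`.
#' @param pair A [salt_bridge_pair()].
#' @param window Moving-average window in frames (>= 1).
#' @return List with `series` (data.frame: frame, distance, moving_avg),
#'   `formed_fraction`, `cutoff` and `errors` (frames skipped).
#' @export
salt_bridge_series <- function(trajectory, pair, window = 1) {
  stopifnot(is_structure_model(trajectory), inherits(pair, "salt_bridge_pair"))
  if (window < 1) stop("window must be >= 1", call. = FALSE)
  at <- trajectory$atoms
  don_i <- which(at$chain == pair$donor$chain & at$resno == pair$donor$resno &
                   trimws(at$elety) %in% pair$donor_atoms)
  acc_i <- which(at$chain == pair$acceptor$chain & at$resno == pair$acceptor$resno &
                   trimws(at$elety) %in% pair$acceptor_atoms)
  n_frames <- trajectory$n_models
  dist <- rep(NA_real_, n_frames)
  errors <- character(0)
  for (f in seq_len(n_frames)) {
    if (!length(don_i) || !length(acc_i)) {
      errors <- c(errors, sprintf("frame %d: missing side-chain atoms", f))
      next
    }
    xyz <- model_coords(trajectory, f)
    dd <- outer(rowSums(xyz[don_i, , drop = FALSE]^2),
                rowSums(xyz[acc_i, , drop = FALSE]^2), "+") -
      2 * xyz[don_i, , drop = FALSE] %*% t(xyz[acc_i, , drop = FALSE])
    dist[f] <- sqrt(max(min(dd), 0))
  }
  ok <- !is.na(dist)
  mov <- zoo::rollapply(zoo::zoo(dist), width = window,
                        FUN = function(v) mean(v, na.rm = TRUE),
                        partial = TRUE, align = "center")
  list(series = data.frame(frame = seq_len(n_frames), distance = dist,
                           moving_avg = as.numeric(mov)),
       formed_fraction = if (any(ok)) mean(dist[ok] < pair$cutoff) else NA_real_,
       cutoff = pair$cutoff, errors = errors)
}

#' Harmonic distance-restraint energy
#'
#' Energy of a set of DEER-derived distance restraints,
#' \eqn{E = \sum_i \tfrac12 k_i (d_i - d_i^{target})^2} by default (the
#' conventional half-k harmonic form; set `half_k = FALSE` for
#' \eqn{k (\Delta d)^2}). Distances are supplied in nm and converted to
#' Angstrom internally to match force constants in kcal/mol/A^2.
#'
#' @param distances Observed per-pair distances, nm. If named, they are
#'   aligned to `restraints$pair`; otherwise positional (lengths must
#'   match).
#' @param restraints Data.frame with columns `pair` (label), `target_nm`
#'   and `k` (kcal/mol/A^2).
#' @param half_k Use the 1/2 k convention (default TRUE).
#' @return List with `total` (kcal/mol) and `per_pair` (data.frame with the
#'   per-restraint terms).
#' @export
restraint_energy <- function(distances, restraints, half_k = TRUE) {
  if (!is.data.frame(restraints) ||
      !all(c("pair", "target_nm", "k") %in% names(restraints)))
    stop("restraints must have columns pair, target_nm, k", call. = FALSE)
  if (any(restraints$target_nm <= 0)) stop("targets must be > 0", call. = FALSE)
  if (any(restraints$k < 0)) stop("force constants must be >= 0", call. = FALSE)
  if (!is.null(names(distances)) && all(names(distances) != "")) {
    miss <- setdiff(restraints$pair, names(distances))
    if (length(miss))
      stop("no distance supplied for pair(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    distances <- distances[restraints$pair]
  } else if (length(distances) != nrow(restraints)) {
    stop("unnamed distances must match restraints row-for-row", call. = FALSE)
  }
  dd_A <- 10 * (as.numeric(distances) - restraints$target_nm)
  fac <- if (half_k) 0.5 else 1
  terms <- fac * restraints$k * dd_A^2
  list(total = sum(terms),
       per_pair = data.frame(pair = restraints$pair,
                             distance_nm = as.numeric(distances),
                             target_nm = restraints$target_nm,
                             k = restraints$k, energy = terms))
}
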