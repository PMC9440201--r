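# Fixtures place four pseudo-atom groups at chosen centers so the angle
# closed forms are known by construction.
four_blob_structure <- function(p_Nin, p_Cin, p_Next = c(0, 0, 5),
                                p_Cext = c(0, 0, -5)) {
  # N-domain residues 1..10, C-domain 11..20; intracellular = first halves.
  # Defaults put the two extracellular halves symmetric about the origin so
  # the alpha vertex (their joint center of mass) is the origin exactly.
  place <- function(resno, center) data.frame(
    elety = "CA", resid = "ALA", chain = "A", resno = resno, elesy = "C",
    x = center[1], y = center[2], z = center[3])
  atoms <- rbind(
    do.call(rbind, lapply(1:5, place, center = p_Nin)),
    do.call(rbind, lapply(6:10, place, center = p_Next)),
    do.call(rbind, lapply(11:15, place, center = p_Cin)),
    do.call(rbind, lapply(16:20, place, center = p_Cext)))
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  make_structure(atoms, coords)
}

test_that("by-sequence domain split gives equal halves with documented tie-break", {
  st <- generate_toy_bundle(n_helices = 2, n_res = 50, bundle_radius = 10)
  expect_error(split_domains(st, 1:50, 40:60), "overlap")
  sp2 <- split_domains(st, 1:50, 51:100)
  expect_equal(length(sp2$N_intra), 25)
  expect_equal(sp2$N_intra, 1:25)
  expect_equal(sp2$C_extra, 76:100)
  # odd count: extra residue goes to the first half
  sp3 <- split_domains(st, 1:51, 52:100)
  expect_equal(length(sp3$N_intra), 26)
  expect_equal(length(sp3$N_extra), 25)
})

test_that("by-z split matches brute-force median assignment", {
  st <- generate_toy_bundle(n_helices = 2, n_res = 30, bundle_radius = 10)
  sp <- split_domains(st, 1:30, 31:60, mode = "by-z")
  ca <- st$atoms[trimws(st$atoms$elety) == "CA" & st$atoms$resno <= 30, ]
  med <- median(ca$z)
  expect_setequal(sp$N_intra, ca$resno[ca$z < med])
  expect_setequal(sp$N_extra, ca$resno[ca$z >= med])
})

test_that("alpha/beta reproduce collinear and right-angle closed forms", {
  # collinear: vertex between the endpoints -> 180 degrees (alpha and beta)
  st <- four_blob_structure(c(-10, 0, 0), c(10, 0, 0))
  sp <- split_domains(st, 1:10, 11:20)
  ab <- compute_alpha_beta(st, sp)
  expect_equal(unname(ab["alpha"]), 180, tolerance = 1e-9)
  expect_equal(unname(ab["beta"]), 180, tolerance = 1e-9)
  # right angle at the alpha vertex
  st90 <- four_blob_structure(c(10, 0, 0), c(0, 10, 0))
  ab90 <- compute_alpha_beta(st90, split_domains(st90, 1:10, 11:20))
  expect_equal(unname(ab90["alpha"]), 90, tolerance = 1e-9)
})

test_that("alpha/beta on a helix bundle match an independent COM + arccos oracle", {
  st <- generate_toy_bundle(n_helices = 12, n_res = 20, bundle_radius = 25)
  sp <- split_domains(st, 1:120, 121:240)
  ab <- compute_alpha_beta(st, sp)
  com <- function(resnos) {
    sel <- st$atoms$resno %in% resnos
    m <- deerfit:::atom_mass(st$atoms$elesy[sel])
    xyz <- as.matrix(st$atoms[sel, c("x", "y", "z")])
    colSums(xyz * m) / sum(m)
  }
  ang <- function(a, v, b) {
    v1 <- a - v; v2 <- b - v
    acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
  }
  alpha_ref <- ang(com(sp$N_intra), com(c(sp$N_extra, sp$C_extra)), com(sp$C_intra))
  beta_ref <- ang(com(sp$N_extra), com(c(sp$N_intra, sp$C_intra)), com(sp$C_extra))
  expect_equal(unname(ab["alpha"]), alpha_ref, tolerance = 1e-9)
  expect_equal(unname(ab["beta"]), beta_ref, tolerance = 1e-9)
  # invariance under global rotation + translation
  th <- 1.1
  R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  xyz <- matrix(st$xyz[1, ], ncol = 3, byrow = TRUE) %*% t(R) +
    matrix(rep(c(7, -2, 3), each = nrow(st$atoms)), ncol = 3)
  str <- make_structure(st$atoms, xyz)
  abr <- compute_alpha_beta(str, sp)
  expect_equal(unname(abr), unname(ab), tolerance = 1e-9)
  # equal-mass fixture: mass-weighted equals geometric
  ab_geo <- compute_alpha_beta(st, sp, mass_weighted = FALSE, ca_only = TRUE)
  ab_ca <- compute_alpha_beta(st, sp, mass_weighted = TRUE, ca_only = TRUE)
  expect_equal(unname(ab_geo), unname(ab_ca), tolerance = 1e-9)
})

test_that("salt-bridge series recovers constructed schedules", {
  # static: constant distance, formed throughout
  sb0 <- generate_saltbridge_trajectory(n_frames = 10, formed = 3, broken = 8,
                                        switch_frame = 10, jitter = 0, seed = 1)
  out0 <- salt_bridge_series(sb0$trajectory, sb0$pair, window = 5)
  expect_equal(out0$series$distance, rep(3, 10), tolerance = 1e-3)
  expect_equal(out0$series$moving_avg, rep(3, 10), tolerance = 1e-3)
  expect_equal(out0$formed_fraction, 1.0)
  # switch schedule: formed first half, broken after
  sb <- generate_saltbridge_trajectory(n_frames = 100, formed = 3, broken = 8,
                                       switch_frame = 50, jitter = 0.2, seed = 2)
  out <- salt_bridge_series(sb$trajectory, sb$pair, window = 10)
  formed_bf <- sb$truth$distances < 4
  expect_equal(out$formed_fraction, mean(formed_bf))
  expect_equal(out$formed_fraction, 0.5, tolerance = 0.5 / 100 + 1e-9)
  expect_equal(which(diff(out$series$distance > 4) == 1), 50)
  # window = 1: moving average equals the raw series
  out1 <- salt_bridge_series(sb$trajectory, sb$pair, window = 1)
  expect_equal(out1$series$moving_avg, out1$series$distance)
  # moving average of (d + c) equals moving average of d plus c: check via a
  # trajectory whose residues are both rigidly shifted (distances unchanged)
  # against a direct zoo computation with an offset
  ma7 <- salt_bridge_series(sb$trajectory, sb$pair, window = 7)$series$moving_avg
  ref <- as.numeric(zoo::rollapply(zoo::zoo(out1$series$distance + 2), 7,
                                   mean, partial = TRUE, align = "center"))
  expect_equal(ma7 + 2, ref, tolerance = 1e-12)
})

test_that("missing side-chain atoms are reported and excluded", {
  sb <- generate_saltbridge_trajectory(n_frames = 5, seed = 3)
  tr <- sb$trajectory
  # drop the acceptor oxygens entirely
  keep <- !(trimws(tr$atoms$elety) %in% c("OD1", "OD2"))
  tr2 <- make_structure(tr$atoms[keep, ],
                        lapply(1:5, function(f)
                          matrix(tr$xyz[f, rep(keep, each = 3)], ncol = 3, byrow = TRUE)))
  out <- salt_bridge_series(tr2, sb$pair)
  expect_equal(length(out$errors), 5)
  expect_true(all(is.na(out$series$distance)))
  expect_true(is.na(out$formed_fraction))
})

test_that("restraint energy follows the half-k harmonic closed form", {
  rs <- data.frame(pair = "p1", target_nm = 3.0, k = 10)
  expect_equal(restraint_energy(3.0, rs)$total, 0)
  # 1 A displacement at k = 10 kcal/mol/A^2 -> 5 kcal/mol
  expect_equal(restraint_energy(3.1, rs)$total, 5.0, tolerance = 1e-12)
  expect_equal(restraint_energy(3.1, rs, half_k = FALSE)$total, 10.0)
  # 5 random pairs against a term-by-term hand summation
  set.seed(12)
  rs5 <- data.frame(pair = paste0("p", 1:5), target_nm = runif(5, 2, 5),
                    k = runif(5, 1, 20))
  d5 <- rs5$target_nm + rnorm(5, 0, 0.1)
  hand <- sum(0.5 * rs5$k * (10 * (d5 - rs5$target_nm))^2)
  expect_equal(restraint_energy(d5, rs5)$total, hand, tolerance = 1e-12)
  # quadratic scaling of displacements
  e1 <- restraint_energy(rs5$target_nm + 0.05, rs5)$total
  e2 <- restraint_energy(rs5$target_nm + 0.10, rs5)$total
  expect_equal(e2 / e1, 4, tolerance = 1e-9)
  # named alignment and mismatch error
  named <- stats::setNames(d5, rev(rs5$pair))
  expect_equal(restraint_energy(named, rs5)$per_pair$distance_nm,
               unname(named[rs5$pair]))
  expect_error(restraint_energy(stats::setNames(d5, paste0("q", 1:5)), rs5),
               "no distance")
  expect_error(restraint_energy(d5[1:3], rs5), "match")
})
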