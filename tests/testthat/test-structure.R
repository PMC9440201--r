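test_that("PDB structures round-trip through write/read", {
  st <- two_residue_fixture()
  path <- file.path(tempdir(), "two_res.pdb")
  write_structure(st, path)
  back <- read_structure(path)
  expect_equal(nrow(back$atoms), 6)
  expect_equal(back$n_models, 1)
  expect_equal(back$atoms$x, st$atoms$x, tolerance = 1e-3)
  expect_equal(back$atoms$resno, st$atoms$resno)
})

test_that("multi-model PDB files load as trajectories", {
  sb <- generate_saltbridge_trajectory(n_frames = 3, seed = 1)
  path <- file.path(tempdir(), "traj3.pdb")
  write_structure(sb$trajectory, path)
  back <- read_structure(path)
  expect_equal(back$n_models, 3)
  expect_equal(nrow(back$atoms), 7)
})

test_that("label sites validate their attachment frame", {
  st <- two_residue_fixture()
  site <- label_site(st, "A", 1)
  expect_equal(unname(site$CB), c(1.5, 0, 0))
  # missing CB -> error naming the site
  st_noCB <- make_structure(st$atoms[-3, ], matrix(st$xyz[1, -(7:9)], ncol = 3,
                                                   byrow = TRUE))
  expect_error(label_site(st_noCB, "A", 1), "A:1.*CB")
  expect_error(label_site(st, "B", 1), "no residue")
  gly <- st
  gly$atoms$resid <- "GLY"
  expect_error(label_site(gly, "A", 1), "glycine")
})

test_that("label clouds obey the tether geometry and are seeded", {
  st <- two_residue_fixture(gap = 30)
  cl <- build_label_cloud(st, "A:1", L = 7, n_samples = 500, seed = 3)
  # isolated site: everything survives and sits exactly L from CB
  expect_equal(cl$survivor_fraction, 1)
  d <- sqrt(rowSums((cl$positions - matrix(1.5, nrow(cl$positions), 3,
                                           byrow = TRUE) %*% diag(c(1, 0, 0)))^2))
  expect_equal(d, rep(7, length(d)), tolerance = 1e-9)
  expect_equal(sum(cl$weights), 1, tolerance = 1e-12)
  cl2 <- build_label_cloud(st, "A:1", L = 7, n_samples = 500, seed = 3)
  expect_identical(cl$positions, cl2$positions)
  expect_false(identical(
    cl$positions, build_label_cloud(st, "A:1", L = 7, n_samples = 500,
                                    seed = 4)$positions))
})

test_that("clash rejection matches brute-force enumeration on a wall fixture", {
  st <- two_residue_fixture(gap = 30)
  # a double wall of atoms at x = 4.5 and x = 6.5 (3 A from residue 1's CB);
  # the second plane blocks the thin reachable shell beyond the first, so
  # every survivor must sit on the open (-x) side
  wall_xy <- expand.grid(y = seq(-12, 12, by = 1), z = seq(-12, 12, by = 1))
  wall <- rbind(cbind(4.5, wall_xy$y, wall_xy$z),
                cbind(6.5, wall_xy$y, wall_xy$z))
  wall_atoms <- data.frame(elety = "O", resid = "HOH", chain = "W",
                           resno = seq_len(nrow(wall)) + 100L, elesy = "O",
                           x = 0, y = 0, z = 0)
  atoms <- rbind(st$atoms, wall_atoms)
  coords <- rbind(matrix(st$xyz[1, ], ncol = 3, byrow = TRUE), wall)
  stw <- make_structure(atoms, coords)
  cutoff <- 2.5
  cl <- build_label_cloud(stw, "A:1", L = 7, n_samples = 800, seed = 11,
                          clash_cutoff = cutoff)
  expect_gt(nrow(cl$positions), 0)
  # brute force over the same candidate set
  keep_bf <- vapply(seq_len(nrow(cl$candidates)), function(i) {
    p <- cl$candidates[i, ]
    env <- rbind(wall, matrix(stw$xyz[1, 10:18], ncol = 3, byrow = TRUE))
    min(sqrt(rowSums(sweep(env, 2, p)^2))) >= cutoff
  }, logical(1))
  expect_identical(unname(cl$kept), keep_bf)
  # survivors all sit on the open half-space in front of the wall
  expect_true(all(cl$positions[, 1] < 4.5))
  # monotonicity: larger cutoff never increases survivors
  surv <- vapply(c(1, 2, 2.8), function(ct)
    nrow(build_label_cloud(stw, "A:1", L = 7, n_samples = 800, seed = 11,
                           clash_cutoff = ct)$positions), numeric(1))
  expect_true(all(diff(surv) <= 0))
})

test_that("buried sites raise an explicit error", {
  st <- two_residue_fixture(gap = 30)
  # a blocker at the tip of a narrow cone: every candidate lies within 1.4 A
  # of it, so a 3 A cutoff rejects the whole cloud
  atoms <- rbind(st$atoms,
                 data.frame(elety = "O", resid = "HOH", chain = "W",
                            resno = 201L, elesy = "O", x = 0, y = 0, z = 0))
  stc <- make_structure(atoms, rbind(matrix(st$xyz[1, ], ncol = 3, byrow = TRUE),
                                     c(9, 0, 0)))
  expect_error(build_label_cloud(stc, "A:1", L = 7, cone_half_angle = 10,
                                 n_samples = 50, seed = 1, clash_cutoff = 3),
               "buried")
})

test_that("predicted distributions match two-point and pairwise-mean oracles", {
  st <- two_residue_fixture(gap = 30)
  mkcloud <- function(pos) structure(
    list(positions = matrix(pos, ncol = 3, byrow = TRUE),
         weights = rep(1 / (length(pos) / 3), length(pos) / 3),
         candidates = NULL, kept = NULL,
         site = list(chain = "A", resno = 1), survivor_fraction = 1),
    class = "label_cloud")
  # two single-point clouds 30 A = 3.0 nm apart
  c1 <- mkcloud(c(0, 0, 0)); c2 <- mkcloud(c(30, 0, 0))
  P <- predict_distribution(c1, c2, distance_grid(2, 4, 0.005), smoothing = 0.05)
  m <- distribution_moments(P)
  expect_equal(unname(m["mean"]), 3.0, tolerance = 1e-3)
  expect_equal(unname(m["sd"]), 0.05, tolerance = 2e-3)
  w <- deerfit:::trapz_weights(P$grid$values)
  expect_equal(sum(w * P$density), 1, tolerance = 1e-6)
  # symmetry in argument order
  P2 <- predict_distribution(c2, c1, distance_grid(2, 4, 0.005), smoothing = 0.05)
  expect_equal(P$density, P2$density, tolerance = 1e-12)
  # 100-point clouds: mean equals the brute-force weighted pairwise mean
  set.seed(7)
  a <- matrix(rnorm(300, sd = 2), ncol = 3)
  b <- matrix(rnorm(300, sd = 2), ncol = 3) + matrix(rep(c(35, 0, 0), each = 100), ncol = 3)
  ca <- mkcloud(as.vector(t(a))); cb <- mkcloud(as.vector(t(b)))
  Pab <- predict_distribution(ca, cb, distance_grid(1.5, 8, 0.01), smoothing = 0.03)
  bf <- mean(vapply(1:100, function(i)
    mean(sqrt(colSums((t(b) - a[i, ])^2))), numeric(1))) / 10
  expect_equal(unname(distribution_moments(Pab)["mean"]), bf, tolerance = 1e-3)
  # grid not covering the distances -> range error
  expect_error(predict_distribution(c1, c2, distance_grid(4, 6, 0.01)),
               "does not cover")
})

test_that("predicted distributions are invariant under rigid-body motion", {
  st <- generate_toy_bundle(n_helices = 4, n_res = 8, bundle_radius = 12)
  g <- distance_grid(0.5, 5, 0.01)
  cl1 <- build_label_cloud(st, "A:2", n_samples = 400, seed = 5)
  cl2 <- build_label_cloud(st, "A:18", n_samples = 400, seed = 6)
  P0 <- predict_distribution(cl1, cl2, grid = g, smoothing = 0.05)
  # rotate + translate the whole structure
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  xyz <- matrix(st$xyz[1, ], ncol = 3, byrow = TRUE) %*% t(R)
  xyz <- xyz + matrix(rep(c(5, -3, 11), each = nrow(xyz)), ncol = 3)
  str <- make_structure(st$atoms, xyz)
  cl1r <- build_label_cloud(str, "A:2", n_samples = 400, seed = 5)
  cl2r <- build_label_cloud(str, "A:18", n_samples = 400, seed = 6)
  Pr <- predict_distribution(cl1r, cl2r, grid = g, smoothing = 0.05)
  # the sampling frame is anchored to the residue's own atoms, so the cloud
  # rotates rigidly with the molecule and distances are bitwise-stable
  expect_identical(cl1$kept, cl1r$kept)
  expect_equal(Pr$density, P0$density, tolerance = 1e-9)
})
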