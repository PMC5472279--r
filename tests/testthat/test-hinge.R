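test_that("PDB reading: CA selection, altloc resolution, bad input", {
  path <- tempfile(fileext = ".pdb")
  xyz <- matrix(c(0, 0, 0, 3.8, 0, 0, 7.6, 0, 0), 3, 3, byrow = TRUE)
  write_pdb_fixture(path, 1:3, xyz)
  m <- read_structure(path)
  expect_identical(nrow(m$atoms), 3L)
  expect_equal(m$atoms$x, xyz[, 1])

  # altloc A/B on residue 2: the higher-occupancy copy wins
  path2 <- tempfile(fileext = ".pdb")
  xyz4 <- rbind(xyz[1, ], c(3.8, 0, 0), c(3.8, 9, 9), xyz[3, ])
  write_pdb_fixture(path2, c(1, 2, 2, 3), xyz4,
                    alt = c(" ", "A", "B", " "), occ = c(1, 0.7, 0.3, 1))
  m2 <- read_structure(path2)
  expect_identical(nrow(m2$atoms), 3L)
  expect_equal(m2$atoms$y[m2$atoms$resno == 2], 0)

  expect_error(read_structure(tempfile()), "cannot read")
  bad <- tempfile(fileext = ".pdb")
  writeLines("this is not a pdb", bad)
  expect_error(read_structure(bad))
  unlink(c(path, path2, bad))
})

test_that("residue pairing keeps only residues present in both models", {
  n <- 60
  xyz <- matrix(rnorm(3 * n), n, 3)
  a <- structure_from_coords(xyz)
  b_at <- structure_from_coords(xyz + 0.1)
  drop <- b_at$atoms$resno %in% 20:25
  b <- b_at; b$atoms <- b_at$atoms[!drop, ]
  dom <- domain_definition(c(1, 30), c(31, 60))
  m <- match_common_ca(a, b, dom)
  expect_identical(m$pdz1$resno, setdiff(1:30, 20:25))
  expect_identical(m$pdz2$resno, 31:60)
  # brute-force set intersection oracle
  expect_identical(m$pdz1$resno,
                   sort(intersect(intersect(a$atoms$resno, b$atoms$resno),
                                  1:30)))
  tiny <- a; tiny$atoms <- tiny$atoms[tiny$atoms$resno %in% c(1, 2, 40:60), ]
  expect_error(match_common_ca(tiny, tiny,
                               domain_definition(c(1, 30), c(31, 60))),
               "fewer than 3")
  expect_error(domain_definition(c(1, 50), c(40, 90)), "disjoint")
})

test_that("Kabsch superposition: exact cases and quaternion oracle", {
  set.seed(81)
  pts <- matrix(rnorm(30), 10, 3)
  id <- superpose(pts, pts)
  expect_equal(id$rotation, diag(3), tolerance = 1e-12)
  expect_lt(id$rmsd, 1e-12)

  Rz <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)   # 90 deg about z
  rot <- superpose(pts %*% t(Rz), pts)
  expect_lt(rot$rmsd, 1e-12)
  ang <- acos((sum(diag(rot$rotation)) - 1) / 2) * 180 / pi
  expect_equal(ang, 90, tolerance = 1e-9)

  for (i in 1:10) {
    A <- matrix(rnorm(30), 10, 3)
    B <- matrix(rnorm(30), 10, 3)
    expect_lt(abs(superpose(A, B)$rmsd - quaternion_rmsd(A, B)), 1e-9)
  }
  line <- cbind(1:5, 0, 0)
  expect_error(superpose(line, line + 1), "degenerate")
})

test_that("superposition is invariant to common rigid transforms", {
  set.seed(82)
  A <- matrix(rnorm(36), 12, 3)
  B <- A + matrix(rnorm(36, 0, 0.3), 12, 3)
  base <- superpose(A, B)$rmsd
  Rq <- superpose(matrix(rnorm(30), 10, 3),
                  matrix(rnorm(30), 10, 3))$rotation
  shift <- c(5, -3, 11)
  A2 <- sweep(A %*% t(Rq), 2, shift, `+`)
  B2 <- sweep(B %*% t(Rq), 2, shift, `+`)
  expect_equal(superpose(A2, B2)$rmsd, base, tolerance = 1e-9)
})

test_that("hinge metrics recover constructed rotations exactly", {
  ts <- gen_two_state(80, 33, c(0.2, -0.4, 1), 0, seed = 5)
  dom <- domain_definition(c(1, 80), c(81, 160))
  a <- structure_from_coords(ts$open_coords)
  b <- structure_from_coords(ts$closed_coords)
  h <- hinge_metrics(a, b, dom)
  expect_equal(h$rotation_deg, 33, tolerance = 1e-9)
  expect_lt(h$pdz1_fit_rmsd_A, 1e-9)
  # analytic displacement rms of the rotated domain
  expect_equal(h$rmsd_pdz2_A,
               sqrt(mean(rowSums((ts$closed_coords[81:160, ] -
                                  ts$open_coords[81:160, ])^2))),
               tolerance = 1e-9)
  expect_equal(abs(sum(h$rotation_axis * ts$true_axis)), 1, tolerance = 1e-9)

  same <- hinge_metrics(a, a, dom)
  expect_equal(same$rotation_deg, 0, tolerance = 1e-9)
  expect_lt(same$rmsd_pdz2_A, 1e-12)
  # swap symmetry: angle and rmsd are direction-independent
  hb <- hinge_metrics(b, a, dom)
  expect_equal(hb$rotation_deg, h$rotation_deg, tolerance = 1e-9)
  expect_equal(hb$rmsd_pdz2_A, h$rmsd_pdz2_A, tolerance = 1e-9)
})

test_that("hinge recovery tolerates coordinate jitter", {
  dom <- domain_definition(c(1, 60), c(61, 120))
  errs <- vapply(1:20, function(s) {
    ts <- gen_two_state(60, 33, c(0, 0, 1), jitter_sd = 0.2, seed = 200 + s)
    h <- hinge_metrics(structure_from_coords(ts$open_coords),
                       structure_from_coords(ts$closed_coords), dom)
    abs(h$rotation_deg - 33)
  }, numeric(1))
  expect_lt(max(errs), 1)
})

test_that("elastic-network modes: minimal system and orthonormality", {
  two <- rbind(c(0, 0, 0), c(3, 0, 0))
  em <- enm_modes(two, cutoff_A = 5, n_modes = 1L)
  expect_identical(em$n_zero_modes, 5L)          # 2 atoms: 5 rigid dof
  m <- matrix(em$modes[, 1], 2, 3, byrow = TRUE)
  # the single internal mode stretches along the bond axis
  expect_equal(abs(m[, 1]) / sqrt(rowSums(m^2)), c(1, 1), tolerance = 1e-8)

  set.seed(91)
  coords <- matrix(rnorm(60, sd = 4), 20, 3)
  em2 <- enm_modes(coords, cutoff_A = 50, n_modes = 4L)
  gram <- t(em2$modes) %*% em2$modes
  expect_equal(gram, diag(4), tolerance = 1e-10)
  expect_error(enm_modes(rbind(coords, c(1e4, 1e4, 1e4)), cutoff_A = 50),
               "disconnected")
})

test_that("analytic ENM Hessian eigenvalues match a numeric oracle", {
  set.seed(92)
  coords <- matrix(rnorm(60, sd = 3), 20, 3)
  em <- enm_modes(coords, cutoff_A = 10, n_modes = 6L)
  Hnum <- numeric_enm_hessian(coords, 10)
  ev <- sort(eigen(Hnum, symmetric = TRUE, only.values = TRUE)$values)
  n0 <- sum(ev < max(ev) * 1e-6)
  expect_identical(n0, em$n_zero_modes)
  expect_equal(em$frequency_sq, ev[n0 + 1:6], tolerance = 1e-5)
})

test_that("mode overlaps are normalised projections onto the transition", {
  set.seed(93)
  coords <- matrix(rnorm(45, sd = 4), 15, 3)
  em <- enm_modes(coords, cutoff_A = 12, n_modes = 3L)
  d1 <- matrix(em$modes[, 1], 15, 3, byrow = TRUE)
  ov <- mode_overlap(em$modes, d1 * 2.5)
  expect_equal(ov$overlap, c(1, 0, 0), tolerance = 1e-9)
  expect_error(mode_overlap(em$modes, d1 * 0), "zero displacement")
  expect_error(mode_overlap(em$modes, d1[1:10, ]), "mismatch")
  rand <- matrix(rnorm(45), 15, 3)
  expect_lte(sum(mode_overlap(em$modes, rand)$overlap^2), 1 + 1e-12)
})

test_that("a pure hinge motion projects mainly on a low-frequency mode", {
  ts <- gen_two_state(40, 15, c(0, 1, 0), 0, seed = 6)
  dom <- domain_definition(c(1, 40), c(41, 80))
  a <- structure_from_coords(ts$open_coords)
  b <- structure_from_coords(ts$closed_coords)
  m <- match_common_ca(a, b, dom)
  fit <- superpose(m$pdz1$b, m$pdz1$a)
  disp <- rbind(fit$transform(m$pdz1$b), fit$transform(m$pdz2$b)) -
    rbind(m$pdz1$a, m$pdz2$a)
  em <- enm_modes(ts$open_coords, cutoff_A = 14, n_modes = 6L)
  ov <- mode_overlap(em$modes, disp)
  expect_lte(which.max(ov$overlap), 3L)
})
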