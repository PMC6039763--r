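# superposition, orientation series, density maps, bound/mode classification

test_that("superpose recovers identity and closed-form rotations exactly", {
  set.seed(31)
  ref <- matrix(rnorm(30), 10, 3)
  fit <- superpose(ref, ref)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-12)
  expect_equal(fit$translation, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(fit$rmsd, 0, tolerance = 1e-12)

  # 180 degrees about x flips the z axis: Rzz = -1
  mob <- ref %*% t(rot_x(pi))
  fit <- superpose(mob, ref)
  expect_equal(fit$rotation[3, 3], -1, tolerance = 1e-10)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
})

test_that("superpose recovers applied random rigid transforms to 1e-10", {
  set.seed(32)
  for (k in 1:20) {
    ref <- matrix(rnorm(30), 10, 3)
    R <- rand_rotation()
    t <- rnorm(3, sd = 3)
    mob <- sweep(ref %*% t(R), 2, t, "+")    # mob = R ref + t
    fit <- superpose(mob, ref)               # must invert that map
    expect_equal(fit$rotation, t(R), tolerance = 1e-10)
    expect_equal(fit$rmsd, 0, tolerance = 1e-10)
    # returned rotations are proper orthogonal
    expect_equal(crossprod(fit$rotation), diag(3), tolerance = 1e-8)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-8)
  }
  # weighted fits too
  w <- runif(10, 0.5, 2)
  ref <- matrix(rnorm(30), 10, 3)
  R <- rand_rotation()
  fit <- superpose(ref %*% t(R), ref, weights = w)
  expect_equal(fit$rotation, t(R), tolerance = 1e-10)
})

test_that("superpose rejects degenerate geometry and tiny inputs", {
  line <- cbind(1:5, 2 * (1:5), -(1:5))
  expect_error(superpose(line, line), "degenerate|collinear")
  expect_error(superpose(matrix(0, 2, 3), matrix(0, 2, 3)), "3 points")
})

test_that("superpose never returns a reflection even for mirrored input", {
  set.seed(33)
  ref <- matrix(rnorm(24), 8, 3)
  mirrored <- ref %*% diag(c(1, 1, -1))
  fit <- superpose(mirrored, ref)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-8)
  expect_gt(fit$rmsd, 0)
})

test_that("orientation_series reports Rzz = cos(theta) for a scripted spin", {
  set.seed(34)
  np <- 12
  prot0 <- matrix(rnorm(3 * np), np, 3)
  prot0 <- sweep(prot0, 2, colMeans(prot0))
  top <- toy_system(600L + seq_len(np), rep("NLOBE", np), c("PC", "PC", "PC"))
  nf <- 25
  thetas <- seq(0, pi, length.out = nf)
  coords <- lapply(thetas, function(th) {
    p <- sweep(prot0 %*% t(rot_x(th)), 2, c(5, 5, 6.5), "+")
    rbind(p, cbind(c(1, 5, 9), c(1, 5, 9), 2))
  })
  traj <- traj_from_coords(top, coords, box = c(10, 10, 12))
  psel <- select_particles(top, species = "PROTEIN")
  msel <- select_particles(top, domain = "LIPID")
  ref <- reference_pose(coords[[1]][1:np, ], psel)
  ser <- orientation_series(traj, psel, msel, ref)
  expect_equal(ser$Rzz, cos(thetas), tolerance = 1e-8)
  expect_equal(ser$dz, rep(6.5 - 2, nf), tolerance = 1e-9)
  expect_true(all(ser$Rzz >= -1 - 1e-9 & ser$Rzz <= 1 + 1e-9))
})

test_that("a protein held in the reference pose gives a constant series", {
  np <- 6
  prot <- rbind(diag(3), -diag(3)) + 0.0
  top <- toy_system(600L + seq_len(np), rep("NLOBE", np), c("PC", "PC", "PC"))
  coords <- replicate(10, rbind(sweep(prot, 2, c(5, 5, 4.5), "+"),
                                cbind(c(1, 5, 9), 5, 0)), simplify = FALSE)
  traj <- traj_from_coords(top, coords, box = c(10, 10, 12))
  psel <- select_particles(top, species = "PROTEIN")
  msel <- select_particles(top, domain = "LIPID")
  ser <- orientation_series(traj, psel, msel)
  expect_equal(ser$Rzz, rep(1, 10), tolerance = 1e-9)
  expect_equal(ser$dz, rep(4.5, 10), tolerance = 1e-9)
  expect_equal(ser$d, rep(4.5, 10), tolerance = 1e-9)
})

test_that("density_map conserves probability and normalizes to its maximum", {
  ser <- data.frame(time = 1:5, Rzz = rep(0.52, 5), dz = rep(4.45, 5),
                    d = rep(4.5, 5))
  dm <- density_map(ser)
  expect_equal(sum(dm$rho), 1, tolerance = 1e-9)
  expect_equal(max(dm$deltaD), 1)
  expect_equal(sum(dm$rho > 0), 1)   # single occupied bin
  expect_equal(dm$rho0, 1)

  # uniform seeded draws: deltaD within 5x sampling error of 1 in every bin
  set.seed(35)
  n <- 1e5
  rzz_edges <- seq(-1, 1, by = 0.25)
  d_edges <- seq(0, 8, by = 1)
  ser2 <- data.frame(time = seq_len(n), Rzz = runif(n, -1, 1),
                     dz = runif(n, 0, 8), d = runif(n, 0, 8))
  dm2 <- density_map(ser2, rzz_edges = rzz_edges, d_edges = d_edges)
  expect_equal(sum(dm2$rho), 1, tolerance = 1e-9)
  nbin <- length(dm2$rho)
  p <- 1 / nbin
  se <- sqrt(p * (1 - p) / n) / p     # relative sampling error per bin
  expect_true(all(abs(dm2$rho / mean(dm2$rho) - 1) <= 5 * se))
  expect_error(density_map(ser, rzz_edges = seq(-1, 0, 0.1),
                           d_edges = seq(20, 30, 1)), "outside")
})

test_that("classify_bound finds maximal dwells and honours min_dwell", {
  mk <- function(dz) data.frame(time = seq_along(dz), Rzz = 1, dz = dz,
                                d = dz)
  expect_equal(nrow(classify_bound(mk(rep(10, 50)), 5, 1)), 0)

  iv <- classify_bound(mk(rep(4.5, 40)), 5.0, 10)
  expect_equal(iv, data.frame(start = 1L, end = 40L))

  dz <- c(rep(8, 20), rep(4, 30), rep(8, 20))
  expect_equal(classify_bound(mk(dz), 5, 20), data.frame(start = 21L, end = 50L))
  expect_equal(nrow(classify_bound(mk(dz), 5, 40)), 0)

  # invariance under time relabeling; no overlaps
  set.seed(36)
  dz <- runif(200, 3, 7)
  s1 <- classify_bound(mk(dz), 5, 5)
  s2 <- classify_bound(transform(mk(dz), time = time * 7 + 3), 5, 5)
  expect_identical(s1, s2)
  if (nrow(s1) > 1) expect_true(all(diff(s1$start) > 0) &&
                                  all(s1$start[-1] > s1$end[-nrow(s1)]))
})

test_that("classify_mode labels lobe engagement as the modes are defined", {
  # 2 N-lobe beads, 2 C-lobe beads, 3 headgroup lipids at z = 2
  top <- toy_system(c(601L, 602L, 641L, 642L),
                    c("NLOBE", "NLOBE", "CLOBE", "CLOBE"),
                    c("PIP2", "PIP2", "PIP2"))
  heads <- cbind(c(4.8, 5.0, 5.2), 5, 2)
  mk_traj <- function(nz, cz) {
    coords <- replicate(12, rbind(c(5, 5, nz), c(5.3, 5, nz),
                                  c(5, 5, cz), c(5.3, 5, cz), heads),
                        simplify = FALSE)
    traj_from_coords(top, coords, box = c(10, 10, 12))
  }
  nsel <- select_particles(top, domain = "NLOBE")
  csel <- select_particles(top, domain = "CLOBE")
  hsel <- select_particles(top, headgroup = TRUE)
  iv <- data.frame(start = 1L, end = 12L)

  m1 <- classify_mode(mk_traj(2.5, 4.5), nsel, csel, hsel, iv, cutoff = 0.8)
  expect_true(all(m1$labels == "MODE1"))
  expect_equal(m1$dominant, "MODE1")

  m2 <- classify_mode(mk_traj(2.5, 2.6), nsel, csel, hsel, iv, cutoff = 0.8)
  expect_true(all(m2$labels == "MODE2"))
  expect_equal(m2$dominant, "MODE2")

  unb <- classify_mode(mk_traj(12, 11), nsel, csel, hsel,
                       data.frame(start = integer(0), end = integer(0)),
                       cutoff = 0.8)
  expect_true(all(unb$labels == "UNBOUND"))
  expect_equal(unb$dominant, "UNBOUND")
})
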