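# interacting-lipid counts, Gaussian fits, residence times, lateral diffusion

test_that("interacting_lipid_count counts molecules, not beads", {
  # one lipid with 3 headgroup beads, all within cutoff of the protein
  top <- topology(
    particle_name = c("BB", "PO4", "P1", "P2"),
    residue_id = c(601L, 1001L, 1001L, 1001L),
    residue_name = c("KIN", "POP2", "POP2", "POP2"),
    molecule_id = c(1L, 2L, 2L, 2L),
    domain_label = c("NLOBE", "LIPID", "LIPID", "LIPID"),
    species = c("PROTEIN", "PIP2", "PIP2", "PIP2"),
    is_headgroup = c(FALSE, TRUE, TRUE, TRUE)
  )
  coords <- rbind(c(5, 5, 5), c(5.3, 5, 5), c(5, 5.3, 5), c(5.3, 5.3, 5))
  traj <- traj_from_coords(top, list(coords, coords + 0), box = c(10, 10, 10))
  psel <- select_particles(top, species = "PROTEIN")
  cnt <- interacting_lipid_count(traj, psel, "PIP2", cutoff = 0.8)
  expect_equal(cnt, c(1L, 1L))
  expect_error(interacting_lipid_count(traj, psel, "PIP3", 0.8), "PIP3")
})

test_that("planted interacting lipids are counted exactly; timecourse is consistent", {
  set.seed(51)
  n <- 30
  top <- toy_system(601L, "NLOBE", rep("PIP2", n))
  prot <- c(10, 10, 10)
  mk_frame <- function(inside_idx) {
    L <- cbind(runif(n, 0, 20), runif(n, 0, 20), 2)   # far plane
    for (i in inside_idx) {
      u <- rnorm(3); u <- u / sqrt(sum(u^2))
      L[i, ] <- prot + 0.6 * u
    }
    rbind(prot, L)
  }
  inside <- list(c(3, 7, 9, 12, 15, 20, 22, 25, 28), integer(0), c(5, 6))
  traj <- traj_from_coords(top, lapply(inside, mk_frame), box = c(20, 20, 20))
  psel <- select_particles(top, species = "PROTEIN")
  cnt <- interacting_lipid_count(traj, psel, "PIP2", cutoff = 0.8)
  expect_equal(cnt, c(9L, 0L, 2L))

  tc <- lipid_timecourse(traj, psel, "PIP2", cutoff = 0.8)
  expect_equal(colSums(tc$matrix), cnt)
  expect_equal(which(tc$matrix[, 1]), c(3, 7, 9, 12, 15, 20, 22, 25, 28))
  expect_equal(which(tc$matrix[, 3]), c(5, 6))
  # monotone in cutoff
  cnt2 <- interacting_lipid_count(traj, psel, "PIP2", cutoff = 1.6)
  expect_true(all(cnt2 >= cnt))
  expect_true(all(cnt2 <= n))
})

test_that("count_distribution_fit is the method of moments", {
  expect_error(count_distribution_fit(7), "2 observations")
  fit <- count_distribution_fit(rep(7, 50))
  expect_equal(fit$mean, 7)
  expect_equal(fit$sd, 0)
  expect_equal(fit$n, 50)

  set.seed(52)
  x <- round(rnorm(3000, mean = 9, sd = 2))
  fit <- count_distribution_fit(x)
  expect_equal(fit$mean, mean(x))            # definitional
  expect_lt(abs(fit$mean - 9), 3 * 2 / sqrt(3000))
  expect_lt(abs(fit$sd - 2), 0.15)

  # restriction to bound frames
  y <- c(rep(0, 40), rep(10, 60))
  fit_b <- count_distribution_fit(y, data.frame(start = 41L, end = 100L))
  expect_equal(fit_b$mean, 10)
  expect_equal(fit_b$n, 60)
})

test_that("residence_times merges gaps and labels persistence", {
  mk_tc <- function(rows) {
    structure(list(species = "PIP2", lipid_ids = seq_len(nrow(rows)),
                   matrix = rows, cutoff = 0.8),
              class = "lipid_timecourse")
  }
  tc <- mk_tc(matrix(TRUE, 1, 100))
  rt <- residence_times(tc, gap_tolerance = 0)
  expect_equal(rt$dwells[[1]], 100L)
  expect_equal(rt$labels$label, "persistent")

  pat <- matrix(as.logical(c(1, 1, 1, 0, 0, 1, 1)), 1)
  expect_equal(residence_times(mk_tc(pat), 0)$dwells[[1]], c(3L, 2L))
  expect_equal(residence_times(mk_tc(pat), 2)$dwells[[1]], 7L)

  none <- mk_tc(matrix(FALSE, 1, 50))
  rt0 <- residence_times(none, 1)
  expect_equal(length(rt0$dwells[[1]]), 0)
  expect_equal(rt0$labels$label, "transient")

  # with zero gap tolerance total dwell equals the number of TRUE entries
  set.seed(53)
  rows <- matrix(runif(20 * 400) < 0.3, 20, 400)
  rt <- residence_times(mk_tc(rows), gap_tolerance = 0)
  expect_equal(vapply(rt$dwells, sum, numeric(1), USE.NAMES = FALSE),
               rowSums(rows))
})

test_that("lateral_diffusion recovers a planted random walk within 10%", {
  # independent oracle: an explicit 2-D random walk with known D, wrapped
  # into the box, fed through the package's unwrapping + MSD fit
  set.seed(54)
  n <- 400; nf <- 400; dt <- 0.5; D <- 0.05
  box <- c(12, 12, 12)
  top <- toy_lipid_topology(rep("PC", n))
  pos <- cbind(runif(n, 0, 12), runif(n, 0, 12))
  coords <- vector("list", nf)
  coords[[1]] <- cbind(pos, 2)
  for (k in 2:nf) {
    pos <- pos + sqrt(2 * D * dt) * matrix(rnorm(2 * n), n, 2)
    pos <- pos %% 12
    coords[[k]] <- cbind(pos, 2)
  }
  traj <- traj_from_coords(top, coords, box = box, dt = dt)
  res <- lateral_diffusion(traj, "PC")
  expect_lt(abs(res$D[["PC"]] - D) / D, 0.10)
  expect_equal(res$msd$PC[1], 0)

  # immobile lipids diffuse nowhere
  still <- traj_from_coords(top, replicate(20, coords[[1]], simplify = FALSE),
                            box = box, dt = dt)
  expect_equal(lateral_diffusion(still, "PC")$D[["PC"]], 0)

  # non-uniform time steps are rejected
  bad <- trajectory(top, list(frame(coords[[1]], box, 0),
                              frame(coords[[2]], box, 1),
                              frame(coords[[3]], box, 3)))
  expect_error(lateral_diffusion(bad, "PC"), "uniform")
})

test_that("PBC unwrapping reproduces the generator's planted diffusion", {
  p <- synthetic_params(n_lipids = 400,
                        composition = c(PC = 0.5, PS = 0, PIP2 = 0.5, PIP3 = 0),
                        D_species = c(PC = 0.06, PS = 0.06, PIP2 = 0.02,
                                      PIP3 = 0.02),
                        n_steps = 1000, save_every = 5, dt = 0.05, seed = 55)
  sim <- simulate_membrane_only(p)
  res <- lateral_diffusion(sim$trajectory, c("PC", "PIP2"))
  expect_lt(abs(res$D[["PC"]] - 0.06) / 0.06, 0.10)
  expect_lt(abs(res$D[["PIP2"]] - 0.02) / 0.02, 0.10)
})
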