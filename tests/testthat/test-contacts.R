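# per-residue lipid contacts and intramolecular contact frequencies

test_that("contact_counts matches planted fixtures and the brute-force oracle", {
  set.seed(41)
  # residue 615 gets exactly 7 PIP2 headgroups inside 0.8 nm, rest far
  top <- toy_system(c(609L, 615L), c("NLOBE", "NLOBE"),
                    rep("PIP2", 10))
  p615 <- c(5, 5, 3)
  dirs <- matrix(rnorm(21), 7, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  near <- sweep(0.7 * dirs, 2, p615, "+")   # exactly radius 0.7 around p615
  far <- cbind(runif(3, 0, 10), runif(3, 0, 10), 15)
  coords <- rbind(c(1, 1, 10), p615, near, far)
  traj <- traj_from_coords(top, list(coords), box = c(20, 20, 20))
  psel <- select_particles(top, species = "PROTEIN")
  lsel <- select_particles(top, headgroup = TRUE)
  cc <- contact_counts(traj, psel, lsel, cutoff = 0.8)
  expect_equal(cc$counts["615", "PIP2", 1], 7L)
  expect_equal(cc$counts["609", "PIP2", 1], 0L)

  # protein far above all headgroups -> all zero
  coords0 <- rbind(c(1, 1, 10), c(2, 2, 10), cbind(runif(10, 0, 20),
                                                   runif(10, 0, 20), 2))
  traj0 <- traj_from_coords(top, list(coords0), box = c(20, 20, 20))
  expect_true(all(contact_counts(traj0, psel, lsel, 0.8)$counts == 0))
})

test_that("contact_counts equals all-pairs 27-image brute force on random systems", {
  set.seed(42)
  top <- toy_system(rep(601:605, each = 3), rep("NLOBE", 15),
                    sample(c("PC", "PS", "PIP2"), 30, replace = TRUE))
  box <- c(6, 6, 6)
  coords <- lapply(1:3, function(k)
    matrix(runif(45 * 3, -2, 8), 45, 3))
  traj <- traj_from_coords(top, coords, box = box)
  psel <- select_particles(top, species = "PROTEIN")
  lsel <- select_particles(top, headgroup = TRUE)
  for (cutoff in c(0.8, 1.5, 2.5)) {
    cc <- contact_counts(traj, psel, lsel, cutoff = cutoff)
    bf <- brute_counts(traj, top, psel$indices + 1, lsel$indices + 1, cutoff)
    expect_equal(unname(cc$counts), unname(bf))
  }
  # cutoff monotonicity, elementwise
  c08 <- contact_counts(traj, psel, lsel, 0.8)$counts
  c10 <- contact_counts(traj, psel, lsel, 1.0)$counts
  expect_true(all(c10 >= c08))
})

test_that("normalization puts the top residue at 1 and is scale invariant", {
  cc <- structure(list(residues = c(601L, 602L, 603L), species = "PIP2",
                       counts = array(c(0, 5, 10), c(3, 1, 1),
                                      dimnames = list(601:603, "PIP2", NULL)),
                       cutoff = 0.8, frames = 1L),
                  class = "contact_counts")
  prof <- normalized_contact_profile(cc)
  expect_equal(unname(prof$normalized[, 1]), c(0, 0.5, 1))

  cc$counts <- cc$counts * 37
  prof2 <- normalized_contact_profile(cc)
  expect_equal(prof2$normalized, prof$normalized)

  cc$counts[] <- 0
  prof0 <- normalized_contact_profile(cc)
  expect_true(all(prof0$normalized == 0))
})

test_that("intramolecular contacts count per-residue frame fractions", {
  top <- toy_system(c(591L, 601L, 641L), c("JM", "NLOBE", "CLOBE"),
                    character(0))
  jm <- select_particles(top, domain = "JM")
  kin <- select_particles(top, domain = c("NLOBE", "CLOBE"))
  # JM bead adjacent to the N-lobe bead in every frame, C-lobe far
  coords <- replicate(8, rbind(c(5, 5, 5), c(5.4, 5, 5), c(9, 9, 9)),
                      simplify = FALSE)
  traj <- traj_from_coords(top, coords, box = c(20, 20, 20))
  freq <- intramolecular_contacts(traj, jm, kin, cutoff = 0.8)
  expect_equal(freq$frequency[freq$residue_id == 601], 1)
  expect_equal(freq$frequency[freq$residue_id == 641], 0)
  expect_equal(freq$frequency[freq$residue_id == 591], 1)
  expect_true(all(freq$frequency >= 0 & freq$frequency <= 1))

  # far apart in all frames -> all zeros
  coords0 <- replicate(4, rbind(c(1, 1, 1), c(8, 8, 8), c(12, 12, 12)),
                       simplify = FALSE)
  traj0 <- traj_from_coords(top, coords0, box = c(20, 20, 20))
  expect_true(all(intramolecular_contacts(traj0, jm, kin, 0.8)$frequency == 0))

  expect_error(intramolecular_contacts(traj, jm, jm, 0.8), "overlap")
})

test_that("on a tethered bound run the JM contacts the N-lobe more than the C-lobe", {
  sim <- simulate_encounter(synthetic_params(
    tether = list(enabled = TRUE, k = 2, anchor = NULL, rest = 1.0),
    n_steps = 6000, save_every = 60, seed = 44))
  top <- sim$trajectory$topology
  sels <- synth_selections(top)
  freq <- intramolecular_contacts(sim$trajectory, sels$jm,
                                  selection(c(sels$nlobe$indices,
                                              sels$clobe$indices)),
                                  cutoff = 1.6)
  fN <- freq$frequency[freq$side == "B" & freq$residue_id %in% 601:640]
  fC <- freq$frequency[freq$side == "B" & freq$residue_id %in% 641:680]
  expect_gt(sum(fN), sum(fC))
})
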