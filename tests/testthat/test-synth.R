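# the Brownian-dynamics generator: determinism, composition, planted truth

test_that("identical params and seed give bit-identical output", {
  p <- synthetic_params(n_lipids = 60, n_steps = 400, save_every = 40,
                        seed = 71)
  a <- simulate_encounter(p)
  b <- simulate_encounter(p)
  expect_identical(lapply(a$trajectory$frames, `[[`, "coordinates"),
                   lapply(b$trajectory$frames, `[[`, "coordinates"))
  expect_identical(a$ground_truth$dz, b$ground_truth$dz)
  expect_identical(a$ground_truth$recruited_ids, b$ground_truth$recruited_ids)
  # a different seed diverges
  c <- simulate_encounter(synthetic_params(n_lipids = 60, n_steps = 400,
                                           save_every = 40, seed = 72))
  expect_false(identical(a$ground_truth$dz, c$ground_truth$dz))
})

test_that("composition uses exact largest-remainder rounding", {
  p <- synthetic_params(n_lipids = 2000,
                        composition = c(PC = 0.90, PS = 0.05, PIP2 = 0.05,
                                        PIP3 = 0),
                        n_steps = 1, save_every = 1, seed = 73)
  sim <- simulate_membrane_only(p)
  tab <- table(sim$trajectory$topology$species[
    sim$trajectory$topology$is_headgroup])
  expect_equal(unname(tab[c("PC", "PS", "PIP2")]), c(1800L, 100L, 100L),
               ignore_attr = TRUE)
  # PIP3 variant mirrors the 83:15:2 membrane
  p3 <- synthetic_params(n_lipids = 100,
                         composition = c(PC = 0.83, PS = 0.15, PIP2 = 0,
                                         PIP3 = 0.02),
                         n_steps = 1, save_every = 1, seed = 73)
  tab3 <- table(simulate_membrane_only(p3)$trajectory$topology$species[
    simulate_membrane_only(p3)$trajectory$topology$is_headgroup])
  expect_equal(unname(tab3[c("PC", "PS", "PIP3")]), c(83L, 15L, 2L),
               ignore_attr = TRUE)
  expect_error(synthetic_params(composition = c(PC = 0.8, PS = 0.1,
                                                PIP2 = 0.05, PIP3 = 0)),
               "sum to 1")
  expect_error(synthetic_params(dt = -1), "dt")
})

test_that("zero diffusion freezes the membrane; ground truth stays in bounds", {
  p <- synthetic_params(n_lipids = 50,
                        D_species = c(PC = 0, PS = 0, PIP2 = 0, PIP3 = 0),
                        n_steps = 100, save_every = 20, seed = 74)
  sim <- simulate_membrane_only(p)
  first <- sim$trajectory$frames[[1]]$coordinates
  last <- sim$trajectory$frames[[length(sim$trajectory$frames)]]$coordinates
  expect_identical(first, last)

  enc <- simulate_encounter(synthetic_params(n_lipids = 50, n_steps = 500,
                                             save_every = 50, seed = 75))
  gt <- enc$ground_truth
  lipid_ids <- unique(enc$trajectory$topology$molecule_id[
    enc$trajectory$topology$species != "PROTEIN"])
  for (ids in gt$recruited_ids) expect_true(all(ids %in% lipid_ids))
  expect_true(all(gt$engaged_patch %in% c("NONE", "P1", "P2", "P1P2",
                                          "CFACE")))
  expect_equal(length(gt$dz), length(enc$trajectory$frames))
})

test_that("the free-diffusion control rarely dwells at the membrane", {
  # no attraction, no tether, started 10 nm above the plane
  fracs <- vapply(1:5, function(s) {
    gt <- simulate_encounter(synthetic_params(
      epsilon = 0, start_z = 10, n_lipids = 60, seed = 760 + s))$ground_truth
    mean(gt$dz <= 5)
  }, numeric(1))
  expect_lt(mean(fracs), 0.10)
})

test_that("planted P1-only engagement is recovered as the dominant patch", {
  gts <- lapply(1:3, function(s)
    simulate_encounter(synthetic_params(
      patch_weights = patch_scenario("p1_only"),
      seed = 770 + s))$ground_truth)
  eng <- unlist(lapply(gts, function(g) g$engaged_patch[g$bound]))
  expect_gte(mean(eng == "P1"), 0.90)
  doms <- vapply(gts, function(g) ground_truth_report(g)$dominant_patch,
                 character(1))
  expect_true(all(doms[vapply(gts, function(g) any(g$bound), logical(1))]
                  == "P1"))
})

test_that("attraction switches PIP2 enrichment on at matched seeds", {
  # tether both runs so the protein sits at the membrane either way and the
  # only difference is the patch attraction
  teth <- list(enabled = TRUE, k = 2, anchor = NULL, rest = 1.0)
  on <- simulate_encounter(synthetic_params(tether = teth, seed = 78))
  off <- simulate_encounter(synthetic_params(tether = teth, epsilon = 0,
                                             seed = 78))
  sels <- synth_selections(on$trajectory$topology)
  c_on <- interacting_lipid_count(on$trajectory, sels$protein, "PIP2")
  c_off <- interacting_lipid_count(off$trajectory, sels$protein, "PIP2")
  expect_gt(mean(c_on), mean(c_off))
})

test_that("ground_truth_report aggregates correctly", {
  gt <- structure(list(
    dz = c(6, 4, 4, 4, 6), bound = c(FALSE, TRUE, TRUE, TRUE, FALSE),
    engaged_patch = c("NONE", "P1", "P1", "P1P2", "NONE"),
    recruited_ids = list(integer(0), c(2L, 3L), 2L, c(2L, 4L, 5L),
                         integer(0)),
    bound_intervals = data.frame(start = 2L, end = 4L),
    D_planted = c(PC = 0.05)), class = "ground_truth")
  rep <- ground_truth_report(gt)
  expect_equal(rep$bound_fraction, 0.6)
  expect_equal(rep$dominant_patch, "P1")
  expect_equal(rep$mean_recruited, mean(c(0, 2, 1, 3, 0)))

  gt$bound[] <- FALSE
  gt$engaged_patch[] <- "NONE"
  rep0 <- ground_truth_report(gt)
  expect_equal(rep0$dominant_patch, "NONE")
})
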