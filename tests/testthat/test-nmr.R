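test_that("the Karplus relation evaluates exactly", {
  A <- 9.5; B <- -1.6; C <- 1.8
  expect_equal(karplus_3j(90), C)
  expect_equal(karplus_3j(0), A + B + C)
  expect_equal(karplus_3j(60), 9.5 * 0.25 - 1.6 * 0.5 + 1.8)  # 3.375
  expect_equal(karplus_3j(180, c(7, -1, 1)), 7 + 1 + 1)
  # averaging over a point distribution equals the pointwise value
  expect_equal(expected_mode_coupling(60, 1e-9), karplus_3j(60),
               tolerance = 1e-9)
})

test_that("r^-6 averaging reproduces two-state arithmetic", {
  oracle <- function(r) mean(r^-6)^(-1 / 6)
  # synthetic two-conformer ensembles via direct construction
  mk <- function(d) {
    cf <- list(xyz = rbind(a = c(0, 0, 0), b = c(d, 0, 0)))
    cf
  }
  ens <- structure(list(conformers = list(mk(2), mk(4)),
                        topology = NULL, seed = 0L, model_hash = ""),
                   class = "glyco_ensemble")
  expect_equal(ensemble_noe_distance(ens, c("a", "b")), oracle(c(2, 4)))
  expect_equal(round(ensemble_noe_distance(ens, c("a", "b")), 3), 2.239)
  ens$conformers[[2]] <- mk(8)
  expect_equal(ensemble_noe_distance(ens, c("a", "b")), oracle(c(2, 8)))
  expect_equal(round(ensemble_noe_distance(ens, c("a", "b")), 3), 2.245)
  # single conformer: plain distance
  ens$conformers <- list(mk(3.3))
  expect_equal(ensemble_noe_distance(ens, c("a", "b")), 3.3)
  # non-increasing as any one conformer distance decreases
  ens$conformers <- list(mk(2), mk(4))
  r0 <- ensemble_noe_distance(ens, c("a", "b"))
  ens$conformers[[2]] <- mk(3.5)
  expect_lte(ensemble_noe_distance(ens, c("a", "b")), r0)
  # explicit weights
  ens$conformers <- list(mk(2), mk(4))
  expect_equal(ensemble_noe_distance(ens, c("a", "b"), weights = c(1, 0)), 2)
  expect_error(ensemble_noe_distance(ens, c("a", "b"), weights = c(2, 1)),
               "sum")
})

test_that("restraint sets validate and round-trip through CSV", {
  df <- data.frame(kind = c("NOE", "noNOE", "scalar3J"),
                   atom1 = c("a", "a", "h1"), atom2 = c("b", "c", "h2"),
                   bound = c(3, 5, 4.2), tolerance = c(NA, NA, 0.5),
                   note = c("", "", "h1|c1|c2|h2"))
  set <- restraint_set(df)
  expect_equal(restraint_count(set), 3)
  f <- withr::local_tempfile(fileext = ".csv")
  write_restraints(set, f)
  expect_equal(read_restraints(f)$restraints$bound, df$bound)
  expect_error(restraint_set(data.frame(kind = "wibble", atom1 = "a",
                                        atom2 = "b", bound = 1)),
               "unknown restraint kind")
  df$bound[1] <- -1
  expect_error(restraint_set(df), "positive")
})

test_that("restraint checking classifies NOE, noNOE and couplings", {
  ens <- fx_ens4()
  # trivial distance cases against a real pair
  r <- ensemble_noe_distance(ens, c("T4 H2", "T4 H3"))
  set <- restraint_set(data.frame(
    kind = c("NOE", "NOE", "noNOE", "noNOE"),
    atom1 = "T4 H2", atom2 = "T4 H3",
    bound = c(r + 1, max(r - 1, 0.1), r - 0.5, r + 2),
    tolerance = NA, note = ""))
  rep <- check_restraints(ens, set)
  expect_equal(rep$satisfied, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(rep$margin[1], 1, tolerance = 1e-9)
  # violated NOE reports the violation distance as a negative margin
  expect_equal(rep$margin[2], -(r - max(r - 1, 0.1)), tolerance = 1e-9)
  expect_error(check_restraints(ens, restraint_set(data.frame(
    kind = "NOE", atom1 = "nope", atom2 = "T4 H3", bound = 3,
    tolerance = NA, note = ""))))
})

test_that("the aminobenzoate internal hydrogen bond verifies geometrically", {
  ens <- fx_ens4()
  set <- restraint_set(data.frame(
    kind = c("hbond", "tempCoeff"),
    atom1 = "X5 N11", atom2 = "X5 O7A",
    bound = c(3.5, -2.6), tolerance = NA,
    note = c("internal H bond", "aniline temperature coefficient")))
  rep <- check_restraints(ens, set)
  expect_true(all(rep$satisfied))
  expect_gt(rep$observed[1], 0.5)   # fraction of conformers with the bond
})

test_that("restraints simulated from an ensemble are satisfied by it", {
  ens <- fx_ens4()
  sim <- simulate_restraints(ens, seed = 2)
  rep <- check_restraints(ens, sim$set)
  expect_equal(attr(rep, "n_satisfied"), attr(rep, "n_total"))
  # requesting a total restraint count is honoured exactly
  sim144 <- simulate_restraints(ens, total = 144, seed = 2)
  expect_equal(restraint_count(sim144$set), 144)
  expect_equal(attr(check_restraints(ens, sim144$set), "n_satisfied"), 144)
  # determinism
  sim2 <- simulate_restraints(ens, seed = 2)
  expect_identical(sim$set, sim2$set)
})

test_that("mode populations are recovered from zero-noise couplings", {
  m <- fx_model(); topo <- fx_topo4(); ens <- fx_ens4()
  sim <- simulate_restraints(ens, model = m, n_noe = 0, n_nonoe = 0,
                             seed = 2)
  fit <- fit_mode_populations(sim$set, m, topo, grid = 0.01,
                              n_per_mode = 50, seed = 5)
  expect_equal(fit$populations, table3_populations, tolerance = 1e-8)
  expect_lt(fit$objective, 1e-12)
  # objective at the true occupancies is a global minimum
  expect_lte(fit$objective, 1e-12)
  # single-mode model: trivially (1)
  m1 <- dynamic_model(
    unimodal = fx_model()$unimodal,
    groups = list(codependent_group(
      "g", c("T4 C2-C3", "T4 C1-C2", "T4 C1-X5 NH11"),
      list(fx_model()$groups[[1]]$modes[[1]]), 1)))
  f1 <- fit_mode_populations(sim$set, m1, topo)
  expect_equal(f1$populations, 1)
})

test_that("noisy couplings limit recovery along the weak direction", {
  # 0.5 Hz coupling noise; the Karplus cos-symmetry leaves one weakly
  # determined simplex direction, so per-seed errors are bounded but not
  # small (see the methods vignette)
  m <- fx_model(); topo <- fx_topo4(); ens <- fx_ens4()
  errs <- vapply(1:8, function(s) {
    sim <- simulate_restraints(ens, model = m, n_noe = 0, n_nonoe = 0,
                               j_noise_sd = 0.5, seed = 300 + s)
    fit <- fit_mode_populations(sim$set, m, topo, grid = 0.01,
                                n_per_mode = 50, seed = 5)
    max(abs(fit$populations - table3_populations))
  }, 0)
  expect_lte(stats::median(errs), 0.25)
  expect_true(all(errs <= 0.6))
})
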