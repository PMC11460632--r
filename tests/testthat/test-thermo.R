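test_that("free energies and entropic terms reproduce published values", {
  # KD 1.09 uM at 25 C -> -8.13 kcal/mol (hexasaccharide reference)
  expect_equal(round(free_energy_from_kd(1.09e-6, 298.15), 2), -8.13)
  expect_equal(round(free_energy_from_kd(1e-6, 298.15), 2), -8.19)
  expect_equal(free_energy_from_kd(1, 300), 0)        # standard state
  expect_error(free_energy_from_kd(-1), "positive")
  # -TdS = dG - dH (octasaccharide reference row)
  expect_equal(entropy_term(-8.89, -7.26), -1.63)
  expect_equal(entropy_term(-8.13, -8.29), 0.16, tolerance = 1e-9)
  expect_equal(entropy_term(3, 3), 0)
})

test_that("percent binding and discrimination ratios reproduce tables", {
  expect_equal(round(percent_binding(0.50, 1.09)), 218)
  expect_equal(round(percent_binding(845, 2200)), 260)
  expect_equal(round(percent_binding(181, 103)), 57)
  expect_equal(round(percent_binding(0.15, 0.31)), 207)
  expect_equal(percent_binding(2, 2), 100)
  expect_equal(round(discrimination_ratio(156, 41), 2), 3.80)
  expect_equal(round(discrimination_ratio(21, 141), 2), 0.15)
  expect_equal(discrimination_ratio(100, 100), 1.00)
  expect_true(is.na(discrimination_ratio(NA, 50)))
  # antitone in the modified KD; reciprocal symmetry
  expect_true(percent_binding(2, 1) < percent_binding(1, 1))
  expect_equal(discrimination_ratio(156, 41) * discrimination_ratio(41, 156),
               1, tolerance = 1e-12)
})

test_that("the Wiseman forward model has the right limits", {
  sch <- titration_data(numeric(18))
  expect_equal(wiseman_heats(1e-6, 0, 1, sch), rep(0, 18))
  # paper schedule: c ~ 27.7, sigmoid with inflection near molar ratio N
  expect_equal(itc_c_value(1.09e-6, 1.04, sch), 27.7, tolerance = 0.01)
  q <- wiseman_heats(1.09e-6, -8.29, 1.04, sch)
  expect_equal(length(q), 18)
  expect_true(all(q < 0))                      # exothermic throughout
  expect_true(abs(q[18]) < 0.15 * abs(q[1]))   # saturating tail
  # steepest decline (inflection) near molar ratio N
  v <- cumsum(sch$injection_volumes)
  ratio <- sch$syringe_conc * (1 - exp(-v / sch$cell_volume)) /
    (sch$cell_conc * exp(-v / sch$cell_volume))
  infl <- ratio[which.max(diff(q))]
  expect_lt(abs(infl - 1.04), 0.35)
  # saturating regime: first injection binds essentially everything injected
  qs <- wiseman_heats(1e-9, -10, 1, sch)
  inj_moles <- sch$syringe_conc * sch$injection_volumes[1]
  expect_equal(qs[1], -10 * inj_moles, tolerance = 0.01)
})

test_that("total heat approaches N dH x cell protein for saturating runs", {
  # overfill convention: exact conservation at saturation
  sch <- titration_data(numeric(60), injection_volumes = 5e-6)
  for (cval in c(50, 500)) {
    n <- 1.0
    kd <- n * sch$cell_conc / cval
    q <- wiseman_heats(kd, -8, n, sch, convention = "overfill")
    total_formed <- -sum(q) / 8
    expect_equal(total_formed, n * sch$cell_conc * sch$cell_volume,
                 tolerance = 0.005)
  }
  # perfusion convention: the exact displacement identity holds, and the
  # shortfall from the ideal bound equals the complex never formed because
  # unbound protein escaped during the pre-saturation injections
  q <- wiseman_heats(sch$cell_conc / 50, -8, 1, sch)
  v <- cumsum(sch$injection_volumes)
  dil <- exp(-v / sch$cell_volume)
  S <- sch$cell_conc * dil
  X <- sch$syringe_conc * (1 - dil)
  b <- S + X + sch$cell_conc / 50
  MX <- (b - sqrt(b^2 - 4 * S * X)) / 2
  displaced <- sum(c(0, MX[-60]) *
                     (1 - exp(-sch$injection_volumes / sch$cell_volume)))
  expect_equal(sum(q), -8 * sch$cell_volume * (MX[60] + displaced),
               tolerance = 1e-9)
  expect_lt(abs(sum(q)) / 8,  sch$cell_conc * sch$cell_volume)
  expect_gt(abs(sum(q)) / 8,  0.9 * sch$cell_conc * sch$cell_volume)
})

test_that("ITC fitting recovers generating parameters", {
  truth <- list(kd = 1.09e-6, dh = -8.29, n = 1.04)
  sim <- simulate_itc(truth$kd, truth$dh, truth$n, noise_sd = 0, seed = 3)
  fit <- fit_itc(sim$data)
  expect_equal(fit$K_D, truth$kd, tolerance = 1e-3)
  expect_equal(fit$delta_H, truth$dh, tolerance = 1e-3)
  expect_equal(fit$N, truth$n, tolerance = 1e-3)
  # thermodynamic identities hold to numerical precision
  expect_equal(fit$delta_G,
               R_KCAL * fit$temperature * log(fit$K_D), tolerance = 1e-12)
  expect_equal(fit$minus_T_delta_S, fit$delta_G - fit$delta_H,
               tolerance = 1e-12)
  # recovery across the c range
  sch <- titration_data(numeric(18))
  for (cval in c(5, 500)) {
    kd <- 1.0 * sch$cell_conc / cval
    simc <- simulate_itc(kd, -6, 1, noise_sd = 0, offset_sd = 0, seed = 4)
    fitc <- fit_itc(simc$data)
    expect_equal(fitc$K_D, kd, tolerance = 1e-3)
  }
  expect_error(fit_itc(titration_data(rep(0, 18))), "degenerate")
  expect_error(fit_itc(titration_data(1:4 * 1e-6)), "at least 6")
})

test_that("the MST 1:1 model and fit behave correctly", {
  # half saturation when ligand = KD and receptor is negligible
  expect_equal(mst_fraction_bound(51e-6, 1e-12, 51e-6), 0.5,
               tolerance = 1e-5)
  expect_equal(mst_fraction_bound(1, 1e-9, 1e-6), 1, tolerance = 1e-5)
  expect_equal(mst_fraction_bound(0, 1e-9, 1e-6), 0)
  # receptor depletion negligible at 10 nM receptor
  expect_equal(mst_fraction_bound(51e-6, 10e-9, 51e-6), 0.5,
               tolerance = 1e-4)
  sim <- simulate_mst(51e-6, noise_sd = 0, seed = 5)
  fit <- fit_mst(sim$data)
  expect_equal(fit$K_D, 51e-6, tolerance = 1e-3)
  expect_error(fit_mst(dose_response(5e-3 / 2^(0:15), rep(700, 16))),
               "flat response")
  expect_error(fit_mst(dose_response(c(1e-3, 1e-4), c(1, 2))), "at least 8")
})

test_that("affinity tables assemble from the published dissociation constants", {
  tab <- build_affinity_table(reference_kd_table())
  row <- tab[tab$oligo == "HA6" & tab$modification == "3AA", ]
  expect_equal(round(row$percent_Link_TSG6), 218)
  expect_equal(round(row$percent_CD44_HABD), 11)
  expect_equal(round(row$discrimination, 1), 19.8, tolerance = 0.35)
  un <- tab[tab$oligo == "HA6" & tab$modification == "", ]
  expect_equal(un$percent_Link_TSG6, 100)
  expect_equal(un$discrimination, 1.00)
  expect_equal(un$hc_substrate, "No")
  # missing partner propagates as NA, not an error
  kt <- data.frame(oligo = "HA6", modification = c("", "6AQ"),
                   protein = "Link_TSG6", kd = c(1.09, 1.56))
  t2 <- build_affinity_table(kt)
  expect_true(is.na(t2$discrimination[t2$modification == "6AQ"]))
  # tetrasaccharide rows never had a calorimetric reference: NA percent
  row4 <- tab[tab$oligo == "HA4" & tab$modification == "3AA", ]
  expect_true(is.na(row4$percent_Link_TSG6))
  expect_equal(round(row4$percent_CD44_HABD), 260)
})
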