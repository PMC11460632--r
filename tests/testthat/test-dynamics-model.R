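test_that("the shipped dynamic model matches the measured codependent system", {
  m <- fx_model()
  expect_length(m$groups, 1)
  expect_equal(mode_populations(m, "T4-X5"), table3_populations)
  expect_length(m$groups[[1]]$modes, 5)
  expect_equal(m$groups[[1]]$modes[[2]][["T4 C1-X5 NH11"]]$mu, 116.9)
  expect_equal(m$groups[[1]]$modes[[1]][["T4 C2-C3"]]$sigma, 20.0)
  # 11 rotatable bonds in total
  expect_length(model_torsion_names(m), 11)
  expect_equal(nrow(validate_model(m)), 0)
})

test_that("population invariants are enforced on construction and load", {
  expect_error(
    codependent_group("g", "t1",
                      list(list(t1 = torsion_mode(0, 5)),
                           list(t1 = torsion_mode(90, 5))),
                      populations = c(0.5, 0.6)),
    "populations sum")
  # within tolerance: renormalised silently
  g <- codependent_group("g", "t1",
                         list(list(t1 = torsion_mode(0, 5)),
                              list(t1 = torsion_mode(90, 5))),
                         populations = c(0.5, 0.500000001))
  expect_equal(sum(g$populations), 1, tolerance = 1e-12)
  expect_error(torsion_mode(0, 0), "sigma")
  expect_error(torsion_spec("t", c("a", "b", "c", "c")), "distinct")
})

test_that("validate_model reports every violation without erroring", {
  m <- fx_model()
  bad <- unclass(m)
  bad$groups[[1]]$modes[[3]][["T4 C1-C2"]]$sigma <- 0
  bad$groups[[1]]$populations <- c(0.4, 0.35, 0.22, 0.06, 0.02)
  class(bad) <- "dynamic_model"
  rep <- validate_model(bad)
  expect_gte(nrow(rep), 2)
  expect_true(any(grepl("sigma", rep$message)))
  expect_true(any(grepl("populations sum", rep$message)))
  # duplicate torsion between unimodal and group
  dup <- unclass(m)
  dup$unimodal[["T4 C2-C3"]] <- torsion_mode(0, 5)
  class(dup) <- "dynamic_model"
  expect_true(any(grepl("duplicate", validate_model(dup)$message)))
})

test_that("JSON round trip preserves the model field-wise", {
  m <- fx_model()
  f <- withr::local_tempfile(fileext = ".json")
  write_dynamic_model(m, f)
  m2 <- load_dynamic_model(f)
  expect_equal(m2$unimodal, m$unimodal)
  expect_equal(m2$groups[[1]]$populations, m$groups[[1]]$populations)
  expect_equal(m2$groups[[1]]$modes, m$groups[[1]]$modes)
  expect_equal(model_hash(m2), model_hash(m))
  # angles wrapped on load
  mw <- dynamic_model(unimodal = list(t = torsion_mode(270, 10)))
  expect_equal(mw$unimodal$t$mu, -90)
})

test_that("CSV models load as flat unimodal lists", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("name,mu,sigma", "phi,60,20"), f)
  m <- load_dynamic_model(f)
  expect_length(m$groups, 0)
  expect_equal(m$unimodal$phi$mu, 60)
  writeLines(c("name,mu,sigma", "phi,60,20", "phi,50,10"), f)
  expect_error(load_dynamic_model(f), "duplicate")
  expect_error(load_dynamic_model("nope.json"), "no such file")
})

test_that("mode populations are reported in mode order, permutation-safe", {
  m <- fx_model()
  expect_error(mode_populations(m, "nope"), "unknown group")
  # permute mode order through serialisation: same multiset, permuted order
  x <- glycodyn:::model_to_list(m)
  x$groups[[1]]$modes <- x$groups[[1]]$modes[c(3, 1, 2, 5, 4)]
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA)
  m2 <- load_dynamic_model(f)
  expect_equal(mode_populations(m2, "T4-X5"),
               table3_populations[c(3, 1, 2, 5, 4)])
  expect_setequal(mode_populations(m2, "T4-X5"), table3_populations)
})
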