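test_that("internal-to-Cartesian construction honours the build tree", {
  topo <- fx_topo4()
  xyz <- build_cartesian(topo, fx_mean_torsions())
  tree <- topo$tree
  for (i in 4:nrow(tree)) {
    d <- sqrt(sum((xyz[tree$atom[i], ] - xyz[tree$ref1[i], ])^2))
    expect_equal(d, tree$length[i], tolerance = 1e-6)
    v1 <- xyz[tree$ref2[i], ] - xyz[tree$ref1[i], ]
    v2 <- xyz[tree$atom[i], ] - xyz[tree$ref1[i], ]
    ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
    expect_equal(ang, tree$angle[i], tolerance = 1e-4)
  }
})

test_that("torsion build/measure round-trips within 1e-4 degrees", {
  topo <- fx_topo4()
  tn <- topology_torsions(topo)
  set.seed(42)
  for (rep in 1:100) {
    tv <- stats::setNames(stats::runif(length(tn), -180, 180), tn)
    xyz <- build_cartesian(topo, tv)
    meas <- vapply(tn, function(nm)
      measure_torsion(xyz, topo$torsion_atoms[[nm]]), 0)
    expect_lt(max(abs(wrap_angle(meas - tv[tn]))), 1e-4)
  }
})

test_that("dihedrals of 0 and 360 degrees give identical coordinates", {
  topo <- fx_topo4()
  tv <- fx_mean_torsions()
  tv["T4 C2-C3"] <- 0
  a <- build_cartesian(topo, tv)
  tv["T4 C2-C3"] <- 360
  b <- build_cartesian(topo, tv)
  expect_equal(a, b, tolerance = 1e-10)
})

test_that("measured dihedral signs follow the planar cis/trans convention", {
  # four points: cis planar -> 0, trans planar -> 180
  p <- rbind(c(1, 1, 0), c(0, 1, 0), c(0, 0, 0), c(1, 0, 0))
  expect_equal(dihedral_angle(p[1, ], p[2, ], p[3, ], p[4, ]), 0)
  p4 <- c(-1, 0, 0)
  expect_equal(abs(dihedral_angle(p[1, ], p[2, ], p[3, ], p4)), 180)
  expect_error(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                              c(3, 0, 0)), "collinear")
})

test_that("group sampling follows the mode occupancies", {
  g <- fx_model()$groups[[1]]
  set.seed(1234)
  draws <- replicate(10000, sample_torsion(g)$mode)
  freq <- tabulate(draws, 5) / 10000
  se <- sqrt(table3_populations * (1 - table3_populations) / 10000)
  expect_true(all(abs(freq - table3_populations) <= 3 * se + 1e-12))
  # degenerate group: a single mode with tiny libration
  g1 <- codependent_group("g", "t",
                          list(list(t = torsion_mode(-60, 1e-6))), 1)
  d <- sample_torsion(g1)
  expect_equal(d$mode, 1L)
  expect_equal(unname(d$angles), -60, tolerance = 1e-4)
})

test_that("ensembles are reproducible, anchored and chirality-preserving", {
  m <- fx_model(); topo <- fx_topo4()
  e1 <- generate_ensemble(m, topo, n = 25, seed = 7)
  e2 <- generate_ensemble(m, topo, n = 25, seed = 7)
  expect_identical(e1$conformers, e2$conformers)
  e3 <- generate_ensemble(m, topo, n = 25, seed = 8)
  expect_false(identical(e1$conformers, e3$conformers))
  # anchor atoms bitwise identical across conformers
  anc <- topo$anchor
  expect_gte(length(anc), 3)
  for (i in 2:25)
    expect_identical(e1$conformers[[i]]$xyz[anc, ],
                     e1$conformers[[1]]$xyz[anc, ])
  # stereocentre signed volumes keep their sign in every conformer
  for (sc in topo$stereocenters) {
    sv <- vapply(e1$conformers, function(cf)
      glycodyn:::signed_volume(cf$xyz, sc[1], sc[2], sc[3], sc[4]), 0)
    expect_true(all(sign(sv) == sign(sv[1])))
    expect_lt(max(abs(sv - sv[1])) / abs(sv[1]), 1e-6)
  }
  # mode labels recorded
  expect_true(all(ensemble_mode_labels(e1) %in% 1:5))
  expect_error(generate_ensemble(m, topo, n = 0, seed = 1))
  e0 <- generate_ensemble(m, topo, n = 1, seed = 1)
  expect_length(e0$conformers, 1)
})

test_that("multi-model PDB output round-trips", {
  e <- generate_ensemble(fx_model(), fx_topo4(), n = 8, seed = 5)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble_pdb(e, f)
  lines <- readLines(f)
  expect_length(grep("^MODEL", lines), 8)
  expect_length(grep("^ENDMDL", lines), 8)
  r <- read_ensemble_pdb(f, fx_topo4())
  expect_equal(r$seed, e$seed)
  expect_identical(ensemble_mode_labels(r), ensemble_mode_labels(e))
  expect_lt(max(abs(r$conformers[[4]]$xyz - e$conformers[[4]]$xyz)), 1e-3)
  # write -> read -> write is byte identical
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble_pdb(r, f2)
  expect_identical(readLines(f), readLines(f2))
  expect_error(write_ensemble_pdb(e, ""), "empty")
})

test_that("topology JSON round-trips and unmodified templates are rigid", {
  topo <- fx_topo4()
  f <- withr::local_tempfile(fileext = ".json")
  write_topology(topo, f)
  t2 <- load_topology(f)
  expect_equal(t2$tree$atom, topo$tree$atom)
  expect_equal(t2$torsion_atoms, topo$torsion_atoms)
  expect_equal(build_cartesian(t2, fx_mean_torsions()),
               build_cartesian(topo, fx_mean_torsions()))
  # unmodified oligomer: no free torsions, all atoms anchored
  tu <- ha_topology(6, "none")
  expect_length(topology_torsions(tu), 0)
  expect_setequal(tu$anchor, tu$atoms$id)
})
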