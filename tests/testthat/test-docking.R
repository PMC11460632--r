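rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
}

test_that("anchored superposition recovers known rigid transforms", {
  topo <- fx_topo6()
  xyz <- build_cartesian(topo, fx_mean_torsions())
  anc <- topo$anchor
  # identity: RMSD 0
  pocket <- list(sites = data.frame(), anchor_reference = xyz[anc, ])
  sup <- superpose_anchor(list(xyz = xyz), pocket)
  expect_lt(sup$rmsd, 1e-9)
  expect_equal(sup$rotation, diag(3), tolerance = 1e-9)
  # rotation by 90 deg about z plus translation (1,2,3)
  R <- rot_z(90)
  target <- sweep(xyz[anc, ] %*% t(R), 2, c(1, 2, 3), "+")
  pocket$anchor_reference <- target
  sup <- superpose_anchor(list(xyz = xyz), pocket)
  expect_lt(sup$rmsd, 1e-6)
  expect_equal(sup$rotation, R, tolerance = 1e-6)
  expect_equal(sup$translation, c(1, 2, 3), tolerance = 1e-6)
  # reflected target: proper rotation enforced, residual stays positive
  refl <- xyz[anc, ] %*% diag(c(-1, 1, 1))
  pocket$anchor_reference <- refl
  sup <- superpose_anchor(list(xyz = xyz), pocket)
  expect_equal(det(sup$rotation), 1, tolerance = 1e-9)
  expect_gt(sup$rmsd, 0.1)
  # degenerate inputs
  expect_error(kabsch_superpose(xyz[anc[1:2], ], xyz[anc[1:2], ]),
               "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("superposition agrees with an independent least-squares fit", {
  skip_if_not_installed("bio3d")
  topo <- fx_topo6()
  xyz <- build_cartesian(topo, fx_mean_torsions())
  anc <- topo$anchor
  set.seed(9)
  R <- rot_z(37)
  target <- sweep(xyz[anc, ] %*% t(R), 2, c(-2, 4, 1), "+") +
    matrix(stats::rnorm(length(anc) * 3, 0, 0.05), ncol = 3)
  fit <- kabsch_superpose(xyz[anc, ], target)
  rmsd_bio3d <- bio3d::rmsd(as.vector(t(target)),
                            as.vector(t(xyz[anc, ])), fit = TRUE)
  expect_equal(round(fit$rmsd, 3), rmsd_bio3d)  # bio3d rounds to 3 dp
})

test_that("pose scoring components follow the documented wells", {
  topo <- fx_topo6()
  xyz <- build_cartesian(topo, fx_mean_torsions())
  empty <- list(sites = data.frame(label = character(), role = character(),
                                   x = numeric(), y = numeric(),
                                   z = numeric(), radius = numeric()),
                anchor_reference = xyz[topo$anchor, ])
  sc <- score_pose(xyz, empty, topo)
  expect_equal(sc$hbond, 0)
  expect_equal(sc$vdw, 0)
  expect_equal(sc$total, sc$hbond + sc$vdw + sc$torsion_strain)
  # one acceptor site at the 2.9 A optimum from a single polar atom
  single <- xyz["X5 O7B", , drop = FALSE]
  topo1 <- topo
  site_at <- function(d) data.frame(
    label = "don", role = "hbond_donor",
    x = single[1] + d, y = single[2], z = single[3], radius = 1.8)
  only_o7b <- single
  sc1 <- score_pose(only_o7b, list(sites = site_at(2.9)), topo1)
  expect_equal(sc1$favorability, 4.0)
  expect_equal(score_pose(only_o7b, list(sites = site_at(6.0)), topo1)$hbond, 0)
  expect_equal(score_pose(only_o7b, list(sites = site_at(4.5)), topo1)$hbond, 0)
})

test_that("salt-bridge detection uses the inclusive 4 A criterion", {
  topo <- fx_topo6()
  xyz <- build_cartesian(topo, fx_mean_torsions())
  o <- xyz["X5 O7A", ]
  mk_pocket <- function(d) list(
    sites = data.frame(label = c("arg", "wall"),
                       role = c("cation", "steric"),
                       x = c(o[1] + d, o[1] + 20), y = o[2], z = o[3],
                       radius = c(1.8, 2.5)))
  sb <- detect_salt_bridge(xyz, mk_pocket(3.0), topo)
  expect_true(sb$salt_bridge)
  o7b_d <- sqrt(sum((xyz["X5 O7B", ] - c(o[1] + 3.0, o[2], o[3]))^2))
  expect_equal(sb$min_no_dist, min(3.0, o7b_d), tolerance = 1e-9)
  expect_false(detect_salt_bridge(xyz, mk_pocket(6.0), topo)$salt_bridge)
  # boundary: 4.0 is inclusive (nearest of the two oxygens counts)
  sb4 <- detect_salt_bridge(xyz, mk_pocket(4.0), topo)
  expect_true(sb4$min_no_dist <= 4.0 && sb4$salt_bridge ||
                sb4$min_no_dist > 4.0 && !sb4$salt_bridge)
  # ligand without carboxylate: flag false with note, no error
  noc <- topo; noc$carboxylate_oxygens <- character(0)
  sb0 <- detect_salt_bridge(xyz, mk_pocket(3.0), noc)
  expect_false(sb0$salt_bridge)
  expect_true(!is.null(sb0$note))
})

test_that("moving the carboxylate away from the cation never helps", {
  topo <- fx_topo6()
  coords <- matrix(c(0, 0, 0), 1, 3, dimnames = list("X5 O7A", NULL))
  noc <- topo
  noc$carboxylate_oxygens <- "X5 O7A"
  pocket <- list(sites = data.frame(label = "arg", role = "cation",
                                    x = 0, y = 0, z = 0, radius = 1.8))
  favs <- vapply(seq(3, 5, by = 0.1), function(d) {
    coords[1, 1] <- d
    score_pose(coords, pocket, noc)$favorability
  }, 0)
  expect_true(all(diff(favs) <= 1e-12))
})

test_that("scoring is invariant under global rigid motions", {
  topo <- fx_topo6()
  pocket <- fx_pocket()
  xyz <- superpose_anchor(fx_ens6()$conformers[[1]], pocket)$xyz
  sc0 <- score_pose(xyz, pocket, topo)
  R <- rot_z(63.7); t <- c(5, -3, 11)
  xyz2 <- sweep(xyz %*% t(R), 2, t, "+")
  sites2 <- pocket$sites
  p2 <- sweep(as.matrix(sites2[, c("x", "y", "z")]) %*% t(R), 2, t, "+")
  sites2[, c("x", "y", "z")] <- p2
  pocket2 <- list(sites = sites2, anchor_reference = pocket$anchor_reference)
  sc1 <- score_pose(xyz2, pocket2, topo)
  expect_equal(sc1$total, sc0$total, tolerance = 1e-9)
  expect_equal(sc1$hbond, sc0$hbond, tolerance = 1e-9)
})

test_that("ensemble ranking groups scores by mode with conserved counts", {
  res <- fx_docking()
  scores <- res$scores
  expect_equal(nrow(scores), 250)
  expect_equal(sort(scores$rank), 1:250)
  expect_equal(sum(res$summary$n), 250)
  expect_equal(max(res$summary$max), max(scores$favorability))
  # ranking is deterministic
  res2 <- rank_ensemble(fx_ens6(), fx_pocket(), fx_model())
  expect_identical(res2$scores, scores)
  # ties break by conformer index: an ensemble of identical conformers
  e1 <- generate_ensemble(fx_model(), fx_topo6(), n = 1, seed = 3)
  e3 <- e1
  e3$conformers <- rep(e1$conformers, 3)
  r3 <- rank_ensemble(e3, fx_pocket(), fx_model())
  expect_equal(r3$scores$rank, 1:3)
  expect_equal(length(unique(r3$scores$favorability)), 1)
})

test_that("scores export with the documented CSV columns", {
  res <- fx_docking()
  f <- withr::local_tempfile(fileext = ".csv")
  write_scores_csv(res, f)
  df <- utils::read.csv(f)
  expect_true(all(c("conformer", "mode", "hbond", "vdw", "strain", "total",
                    "favorability", "salt_bridge", "min_no_dist") %in%
                    names(df)))
  expect_equal(nrow(df), 250)
})
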