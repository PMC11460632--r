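# Shared fixtures, built once per test run (all generated in code).

.fixtures <- new.env(parent = emptyenv())

fx <- function(name, expr) {
  if (!exists(name, envir = .fixtures))
    assign(name, expr, envir = .fixtures)
  get(name, envir = .fixtures)
}

fx_topo4 <- function() fx("topo4", ha_topology(4, "2AA"))
fx_topo6 <- function() fx("topo6", ha_topology(6, "2AA"))
fx_model <- function() fx("model", ha4_2aa_model())
fx_ens4 <- function() fx("ens4",
  generate_ensemble(fx_model(), fx_topo4(), n = 300, seed = 21))
fx_ens6 <- function() fx("ens6",
  generate_ensemble(fx_model(), fx_topo6(), n = 250, seed = 11))
fx_pocket <- function() fx("pocket",
  make_pocket_fixture(topology = fx_topo6(), model = fx_model())$pocket)
fx_docking <- function() fx("docking",
  rank_ensemble(fx_ens6(), fx_pocket(), fx_model()))

# mode-1 torsion means of the shipped model (every torsion at its mean)
fx_mean_torsions <- function(mode = 1) {
  m <- fx_model()
  tv <- vapply(m$unimodal, `[[`, 0, "mu")
  g <- m$groups[[1]]
  for (tn in g$torsions) tv[tn] <- g$modes[[mode]][[tn]]$mu
  tv
}

table3_populations <- c(0.35, 0.35, 0.22, 0.06, 0.02)
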