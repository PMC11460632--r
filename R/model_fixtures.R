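# Shipped dynamic-model fixture for the 2AA-modified reducing terminus.

#' Dynamic torsion model of the 2AA-modified HA reducing terminus
#'
#' The measured solution behaviour of the opened GlcNAc / 2-aminobenzoate
#' terminus: three backbone torsions of the opened ring (T4 C2-C3, T4 C1-C2
#' and T4 C1-X5 NH11) are codependent and jointly occupy five librational
#' modes with occupancies 0.35, 0.35, 0.22, 0.06 and 0.02; the remaining
#' eight rotatable bonds of the G3-T4-X5 region are unimodal. The
#' codependent-mode means and libration widths are the experimentally
#' determined values; the unimodal means are representative values chosen
#' for the shipped template (exo-anomeric glycosidic geometry, extended
#' open-chain rotamers, planar internally hydrogen-bonded aminobenzoate)
#' and documented in the methods vignette.
#'
#' @return a `dynamic_model` with one codependent group (`"T4-X5"`, five
#'   modes over three torsions) and eight unimodal torsions.
#' @export
ha4_2aa_model <- function() {
  tm <- torsion_mode
  group <- codependent_group(
    id = "T4-X5",
    torsions = c("T4 C2-C3", "T4 C1-C2", "T4 C1-X5 NH11"),
    modes = list(
      list("T4 C2-C3" = tm(60, 20.0),  "T4 C1-C2" = tm(-60, 4.7),
           "T4 C1-X5 NH11" = tm(-127, 4.4)),
      list("T4 C2-C3" = tm(180, 20.0), "T4 C1-C2" = tm(-60, 4.7),
           "T4 C1-X5 NH11" = tm(116.9, 4.4)),
      list("T4 C2-C3" = tm(180, 20.0), "T4 C1-C2" = tm(-60, 4.7),
           "T4 C1-X5 NH11" = tm(-95.8, 4.4)),
      list("T4 C2-C3" = tm(-60, 20.0), "T4 C1-C2" = tm(180, 4.7),
           "T4 C1-X5 NH11" = tm(-146.9, 4.4)),
      list("T4 C2-C3" = tm(-60, 20.0), "T4 C1-C2" = tm(180, 4.7),
           "T4 C1-X5 NH11" = tm(85.3, 4.4))),
    populations = c(0.35, 0.35, 0.22, 0.06, 0.02))

  unimodal <- list(
    "G3-T4 phi"  = tm(-75, 10),
    "G3-T4 psi"  = tm(120, 10),
    "T4 C3-C4"   = tm(180, 8),
    "T4 C4-C5"   = tm(-60, 8),
    "T4 C5-C6"   = tm(180, 12),
    "X5 N11-C7"  = tm(180, 8),
    "X5 C8-C13"  = tm(0, 6),
    "G3 C5-C6"   = tm(60, 15))

  dynamic_model(
    unimodal = unimodal, groups = list(group),
    metadata = "2AA-modified HA reducing terminus: 11 rotatable bonds, five codependent modes")
}
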