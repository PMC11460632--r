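# Published dissociation constants for modified HA oligosaccharides.

#' Published reference affinities for modified HA oligosaccharides
#'
#' Dissociation constants (and, for the calorimetric series, stoichiometry
#' and thermodynamic decomposition) reported for reducing-end modified HA
#' oligosaccharides binding the Link module of TSG-6 (by isothermal
#' titration calorimetry at 25 C, pH 6.0) and the CD44 HA-binding domain
#' (by microscale thermophoresis at 25 C, pH 7.5). Rows with an empty
#' `modification` are the unmodified oligomers that serve as the 100%
#' references for [percent_binding()]. `hc_substrate` is the categorical
#' outcome of heavy-chain transfer assays.
#'
#' @return data.frame with columns `oligo`, `modification`, `protein`,
#'   `method`, `kd_uM`, `kd_err_uM`, `N`, `dG`, `dH`, `mTdS` (kcal/mol)
#'   and `hc_substrate`.
#' @export
reference_affinities <- function() {
  path <- system.file("extdata", "reference_affinities.csv",
                      package = "glycodyn", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(modification = "character"))
  df$modification[is.na(df$modification)] <- ""
  df
}

#' Reference affinities in the layout of [build_affinity_table()]
#'
#' @return data.frame with columns `oligo`, `modification`, `protein`,
#'   `kd` (uM) and `hc_substrate`.
#' @export
reference_kd_table <- function() {
  df <- reference_affinities()
  data.frame(oligo = df$oligo, modification = df$modification,
             protein = df$protein, kd = df$kd_uM,
             hc_substrate = df$hc_substrate, stringsAsFactors = FALSE)
}
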