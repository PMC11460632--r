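# Binding thermodynamics: single-site (Wiseman) ITC isotherm with
# perfusion-cell bookkeeping, 1:1 MST binding model, thermodynamic
# decomposition, and relative-affinity / discrimination tables.

#' Gas constant in kcal mol^-1 K^-1
#' @export
R_KCAL <- 1.98720425e-3

#' Standard free energy of binding from a dissociation constant
#'
#' `dG = RT ln(KD / 1 M)` (1 M standard state).
#'
#' @param kd dissociation constant, mol/L (> 0).
#' @param temperature absolute temperature, K (default 298.15 K, i.e.
#'   25 C).
#' @return free energy in kcal/mol (negative for sub-molar KD).
#' @export
free_energy_from_kd <- function(kd, temperature = 298.15) {
  if (any(kd <= 0) || any(temperature <= 0))
    stop("kd and temperature must be positive")
  R_KCAL * temperature * log(kd)
}

#' Entropic term -TdS from dG and dH
#'
#' `-TdS = dG - dH`.
#' @param delta_G,delta_H free energy and enthalpy, kcal/mol.
#' @return `-TdS` in kcal/mol.
#' @export
entropy_term <- function(delta_G, delta_H) delta_G - delta_H

#' Percent binding affinity relative to an unmodified reference
#'
#' The association-constant ratio x100: `100 * kd_reference /
#' kd_modified`, i.e. values above 100 mean the modification increased
#' affinity.
#'
#' @param kd_modified KD of the modified oligosaccharide (mol/L or any
#'   consistent unit).
#' @param kd_reference KD of the unmodified oligosaccharide of the same
#'   length (same unit).
#' @return percentage (numeric).
#' @export
percent_binding <- function(kd_modified, kd_reference) {
  if (any(kd_modified <= 0) || any(kd_reference <= 0))
    stop("dissociation constants must be positive")
  100 * kd_reference / kd_modified
}

#' Relative discrimination ratio between two binding partners
#'
#' Ratio of the percent binding affinities for the two proteins; `NA`
#' propagates when either side is missing (not an error).
#'
#' @param pct_tsg6 percent binding affinity for the first protein.
#' @param pct_cd44 percent binding affinity for the second protein.
#' @return `pct_tsg6 / pct_cd44`, or `NA` when either is missing.
#' @export
discrimination_ratio <- function(pct_tsg6, pct_cd44) {
  ifelse(is.na(pct_tsg6) | is.na(pct_cd44), NA_real_,
         ifelse(pct_tsg6 <= 0 | pct_cd44 <= 0, NA_real_,
                pct_tsg6 / pct_cd44))
}

# ---- ITC ----------------------------------------------------------------

#' Titration schedule and data container
#'
#' @param heats per-injection heats, kcal.
#' @param cell_conc protein concentration in the cell, mol/L.
#' @param syringe_conc ligand concentration in the syringe, mol/L.
#' @param cell_volume active cell volume, L.
#' @param injection_volumes per-injection volumes, L (recycled to the
#'   length of `heats` when scalar).
#' @param temperature K.
#' @return object of class `titration_data`.
#' @export
titration_data <- function(heats, cell_conc = 0.029e-3,
                           syringe_conc = 0.29e-3, cell_volume = 200e-6,
                           injection_volumes = 2e-6,
                           temperature = 298.15) {
  if (length(injection_volumes) == 1L)
    injection_volumes <- rep(injection_volumes, length(heats))
  if (length(injection_volumes) != length(heats))
    stop("injection volume / heat lengths differ")
  if (cell_conc <= 0 || syringe_conc <= 0 || cell_volume <= 0)
    stop("concentrations and volumes must be positive")
  structure(list(heats = as.numeric(heats), cell_conc = cell_conc,
                 syringe_conc = syringe_conc, cell_volume = cell_volume,
                 injection_volumes = as.numeric(injection_volumes),
                 temperature = temperature),
            class = "titration_data")
}

#' Predicted per-injection heats for a single-site isotherm
#'
#' Perfusion (overflow) cell bookkeeping: after cumulative injected volume
#' v the cell retains a fraction `exp(-v/V0)` of its original contents, so
#' binding-site and ligand concentrations follow `N*M0*exp(-v/V0)` and
#' `Xs*(1-exp(-v/V0))`. The bound concentration is the analytic root of
#' the single-site quadratic; the heat of injection i is the enthalpy of
#' newly formed complex, crediting complex displaced from the cell during
#' the injection:
#' `q_i = V0 * dH * ([MX]_i - [MX]_(i-1) * exp(-dV_i/V0))`.
#'
#' @param kd dissociation constant, mol/L.
#' @param dh binding enthalpy, kcal/mol of injectant bound.
#' @param n stoichiometry (sites per protein).
#' @param schedule a `titration_data` (its `heats` are ignored).
#' @param convention `"perfusion"` (default; displaced volume leaves the
#'   cell, as in overflow-cell instruments) or `"overfill"` (the cell
#'   volume grows by the injected volume and no material leaves; total
#'   heat then converges exactly to `N * dH * cell protein moles` at
#'   saturation). Under perfusion a few percent of the protein is
#'   displaced unbound during the pre-saturation injections, so the total
#'   heat falls correspondingly short of that bound.
#' @return numeric vector of per-injection heats, kcal.
#' @export
wiseman_heats <- function(kd, dh, n, schedule,
                          convention = c("perfusion", "overfill")) {
  if (kd <= 0 || n <= 0) stop("kd and n must be positive")
  convention <- match.arg(convention)
  v <- cumsum(schedule$injection_volumes)
  V0 <- schedule$cell_volume
  if (convention == "perfusion") {
    dil <- exp(-v / V0)
    S <- n * schedule$cell_conc * dil               # binding sites
    X <- schedule$syringe_conc * (1 - dil)          # total ligand
    b <- S + X + kd
    MX <- (b - sqrt(b^2 - 4 * S * X)) / 2
    MX_prev <- c(0, MX[-length(MX)])
    step_dil <- exp(-schedule$injection_volumes / V0)
    V0 * dh * (MX - MX_prev * step_dil)
  } else {
    Vi <- V0 + v
    S <- n * schedule$cell_conc * V0 / Vi
    X <- schedule$syringe_conc * v / Vi
    b <- S + X + kd
    MX <- (b - sqrt(b^2 - 4 * S * X)) / 2
    moles <- MX * Vi
    dh * diff(c(0, moles))
  }
}

#' Molar c-value of a titration
#'
#' `c = N * [cell] / KD`; sigmoidal isotherms need roughly c in 5-500.
#' @param kd,n,schedule as in [wiseman_heats()].
#' @return dimensionless c-value.
#' @export
itc_c_value <- function(kd, n, schedule) n * schedule$cell_conc / kd

#' Result of a binding-model fit
#'
#' @param kd mol/L; @param dh kcal/mol; @param n stoichiometry;
#' @param temperature K; @param se named numeric standard errors.
#' @return object of class `binding_result` with derived `delta_G` and
#'   `minus_T_delta_S` satisfying `dG = RT ln KD` and `-TdS = dG - dH`
#'   exactly (internal precision).
#' @export
binding_result <- function(kd, dh, n = NA_real_, temperature = 298.15,
                           se = c(kd = NA_real_, dh = NA_real_, n = NA_real_)) {
  dg <- free_energy_from_kd(kd, temperature)
  structure(list(K_D = kd, delta_H = dh, N = n, delta_G = dg,
                 minus_T_delta_S = entropy_term(dg, dh),
                 temperature = temperature, se = se),
            class = "binding_result")
}

#' @export
print.binding_result <- function(x, ...) {
  cat(sprintf(
    "Binding result: KD = %.4g uM, dG = %.2f, dH = %.2f, -TdS = %.2f kcal/mol%s\n",
    x$K_D * 1e6, x$delta_G, x$delta_H, x$minus_T_delta_S,
    if (is.finite(x$N)) sprintf(", N = %.3f", x$N) else ""))
  invisible(x)
}

#' Fit a single-site binding model to ITC data
#'
#' The dilution offset is taken as the mean of the final three injection
#' heats and subtracted from every heat; because the final injections
#' retain a small residual binding heat, the same last-three-mean
#' subtraction is applied to the model prediction inside the fit, making
#' the estimator exact for offset-shifted forward-model data.
#' Levenberg-Marquardt least squares on (log KD, dH, N) over a
#' deterministic multi-start grid (KD in {0.01, 0.1, 1, 10, 100} uM x dH
#' in {-20, -10, -5, -1} kcal/mol, N starting at 1); the best-converged
#' start wins. Standard errors come from the fit covariance.
#'
#' @param data a `titration_data` (>= 6 injections).
#' @return a `binding_result` (with `fit` attributes: residual standard
#'   error, convergence info).
#' @export
fit_itc <- function(data) {
  if (length(data$heats) < 6L) stop("need at least 6 injections")
  offset <- mean(utils::tail(data$heats, 3))
  y <- data$heats - offset
  if (all(abs(y) < .Machine$double.eps * 100))
    stop("degenerate titration: all heats equal")
  resid_fun <- function(par) {
    q <- wiseman_heats(exp(par[1]), par[2], par[3], data)
    q - mean(utils::tail(q, 3)) - y
  }
  starts <- expand.grid(kd = c(0.01, 0.1, 1, 10, 100) * 1e-6,
                        dh = c(-20, -10, -5, -1))
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = c(log(starts$kd[s]), starts$dh[s], 1),
                         fn = resid_fun,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("ITC fit failed to converge from every start")
  p <- best$par
  kd <- exp(p[1]); dh <- p[2]; n <- p[3]
  se <- rep(NA_real_, 3)
  cv <- tryCatch(solve(best$hessian) *
                   best$deviance / max(1, length(y) - 3),
                 error = function(e) NULL)
  if (!is.null(cv)) {
    se <- sqrt(pmax(0, diag(cv)))
    se[1] <- se[1] * kd            # delta method: log KD -> KD
  }
  out <- binding_result(kd, dh, n, data$temperature,
                        se = c(kd = se[1], dh = se[2], n = se[3]))
  attr(out, "fit") <- list(deviance = best$deviance, offset = offset,
                           info = best$info)
  out
}

# ---- MST ----------------------------------------------------------------

#' Dose-response container for MST titrations
#'
#' @param ligand_concs ligand (titrant) concentrations, mol/L.
#' @param responses normalised fluorescence changes, per mil.
#' @param receptor_conc labelled receptor concentration, mol/L.
#' @param temperature K.
#' @return object of class `dose_response`.
#' @export
dose_response <- function(ligand_concs, responses, receptor_conc = 10e-9,
                          temperature = 298.15) {
  if (length(ligand_concs) != length(responses))
    stop("concentration / response lengths differ")
  if (any(ligand_concs <= 0)) stop("ligand concentrations must be positive")
  structure(list(ligand_concs = as.numeric(ligand_concs),
                 responses = as.numeric(responses),
                 receptor_conc = receptor_conc, temperature = temperature),
            class = "dose_response")
}

#' Fraction of receptor bound under a 1:1 model
#'
#' Exact quadratic solution (no free-ligand approximation):
#' `[RL] = ((R+L+KD) - sqrt((R+L+KD)^2 - 4 R L)) / 2`, returned as
#' `[RL]/R`.
#'
#' @param ligand_total total ligand concentration(s), mol/L.
#' @param receptor_total total receptor concentration, mol/L.
#' @param kd dissociation constant, mol/L.
#' @return fraction bound in [0, 1].
#' @export
mst_fraction_bound <- function(ligand_total, receptor_total, kd) {
  if (kd <= 0) stop("kd must be positive")
  if (any(ligand_total < 0) || any(receptor_total < 0))
    stop("concentrations must be non-negative")
  if (all(receptor_total == 0)) return(rep(0, length(ligand_total)))
  b <- ligand_total + receptor_total + kd
  rl <- (b - sqrt(b^2 - 4 * ligand_total * receptor_total)) / 2
  rl / receptor_total
}

#' Fit a 1:1 binding model to an MST dose-response
#'
#' `dFnorm = baseline + amplitude * fraction_bound(L, R, KD)`, least
#' squares on (log KD, baseline, amplitude) with a deterministic start
#' grid of KD spanning the titrated concentration range.
#'
#' @param data a `dose_response` (>= 8 points).
#' @return a `binding_result` with `N = NA` (stoichiometry fixed at 1:1)
#'   and `dH = NA`; `baseline` and `amplitude` in the `fit` attribute.
#' @export
fit_mst <- function(data) {
  if (length(data$ligand_concs) < 8L) stop("need at least 8 dose points")
  y <- data$responses
  if (stats::sd(y) < 1e-12 * max(1, abs(mean(y))))
    stop("flat response: amplitude indistinguishable from 0")
  resid_fun <- function(par) {
    fb <- mst_fraction_bound(data$ligand_concs, data$receptor_conc,
                             exp(par[1]))
    par[2] + par[3] * fb - y
  }
  kd_starts <- exp(seq(log(min(data$ligand_concs)),
                       log(max(data$ligand_concs)), length.out = 7))
  best <- NULL
  for (k0 in kd_starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = c(log(k0), min(y), diff(range(y)) *
                                   sign(y[length(y)] - y[1])),
                         fn = resid_fun,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("MST fit failed to converge from every start")
  p <- best$par
  kd <- exp(p[1])
  se <- rep(NA_real_, 3)
  cv <- tryCatch(solve(best$hessian) *
                   best$deviance / max(1, length(y) - 3),
                 error = function(e) NULL)
  if (!is.null(cv)) {
    se <- sqrt(pmax(0, diag(cv)))
    se[1] <- se[1] * kd
  }
  out <- binding_result(kd, NA_real_, NA_real_, data$temperature,
                        se = c(kd = se[1], dh = NA, n = NA))
  attr(out, "fit") <- list(deviance = best$deviance, baseline = p[2],
                           amplitude = p[3],
                           se_baseline = se[2], se_amplitude = se[3])
  out
}

# ---- affinity tables -----------------------------------------------------

#' Build a relative-affinity / discrimination table
#'
#' For each oligosaccharide length x modification, computes the percent
#' binding affinity against the unmodified oligomer of the same length for
#' each protein, and the discrimination ratio between the two proteins;
#' missing measurements propagate as `NA` ("n.d.").
#'
#' @param kd_table data.frame with columns `oligo` (e.g. "HA6"),
#'   `modification` ("" or "none" for unmodified), `protein`, `kd`
#'   (consistent unit per protein) and optionally `hc_substrate`
#'   ("Yes"/"No").
#' @param proteins length-2 character vector: the numerator and
#'   denominator protein of the discrimination ratio.
#' @return data.frame with one row per oligo/modification: `percent_` per
#'   protein, `discrimination`, `hc_substrate`.
#' @export
build_affinity_table <- function(kd_table,
                                 proteins = c("Link_TSG6", "CD44_HABD")) {
  kt <- kd_table
  if (!"hc_substrate" %in% names(kt)) kt$hc_substrate <- NA_character_
  kt$modification[is.na(kt$modification)] <- ""
  kt$modification[kt$modification == "none"] <- ""
  key <- unique(kt[, c("oligo", "modification")])
  ref_kd <- function(oligo, protein) {
    i <- which(kt$oligo == oligo & kt$modification == "" &
                 kt$protein == protein)
    if (length(i) == 0L) NA_real_ else kt$kd[i[1]]
  }
  rows <- lapply(seq_len(nrow(key)), function(r) {
    oligo <- key$oligo[r]; m <- key$modification[r]
    pct <- vapply(proteins, function(p) {
      i <- which(kt$oligo == oligo & kt$modification == m & kt$protein == p)
      if (length(i) == 0L) return(NA_real_)
      ref <- ref_kd(oligo, p)
      if (is.na(ref)) stop("missing unmodified reference for ", oligo,
                           " / ", p)
      percent_binding(kt$kd[i[1]], ref)
    }, 0)
    hc <- NA_character_
    i <- which(kt$oligo == oligo & kt$modification == m &
                 !is.na(kt$hc_substrate))
    if (length(i) > 0L) hc <- kt$hc_substrate[i[1]]
    data.frame(oligo = oligo, modification = m,
               percent_1 = pct[1], percent_2 = pct[2],
               discrimination = discrimination_ratio(pct[1], pct[2]),
               hc_substrate = hc, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[names(out) == "percent_1"] <- paste0("percent_", proteins[1])
  names(out)[names(out) == "percent_2"] <- paste0("percent_", proteins[2])
  out
}
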