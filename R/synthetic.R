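# Synthetic-data generators: every pipeline input with known ground truth.
#
# Each generator is a pure function of (truth, seed) and returns the
# dataset together with a truth record; identical seeds reproduce datasets
# bit-exactly.

#' Truth record accompanying a simulated dataset
#'
#' @param parameters named list of generating parameters.
#' @param seed integer seed used.
#' @param noise free-text description of the noise model.
#' @return object of class `truth_record`.
#' @export
truth_record <- function(parameters, seed, noise = "none") {
  structure(list(parameters = parameters, seed = as.integer(seed),
                 noise = noise),
            class = "truth_record")
}

#' Write / read a truth record (JSON round trip)
#' @param truth a `truth_record`.
#' @param path file path.
#' @return `path` invisibly / the restored `truth_record`.
#' @export
write_truth_record <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth_record
#' @export
read_truth_record <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  truth_record(x$parameters, x$seed, x$noise)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

#' Simulate an ITC titration
#'
#' Forward heats from [wiseman_heats()] under the standard schedule
#' (18 x 2 ul injections of 0.29 mM ligand into 200 ul of 0.029 mM
#' protein at 25 C), plus a constant dilution offset (drawn once) and
#' i.i.d. Gaussian noise with sd = `noise_sd` x max |heat|.
#'
#' @param kd,dh,n generating parameters (mol/L, kcal/mol, sites).
#' @param schedule a `titration_data` supplying the injection geometry;
#'   default is the standard schedule above.
#' @param noise_sd noise fraction (default 0.01 = 1% of the largest heat).
#' @param offset_sd dilution-offset scale as a fraction of the largest
#'   heat (default 0.02); the offset is drawn once per dataset.
#' @param seed integer seed.
#' @return list with `data` (a `titration_data`) and `truth`
#'   (a `truth_record`).
#' @export
simulate_itc <- function(kd, dh, n = 1, schedule = NULL, noise_sd = 0.01,
                         offset_sd = 0.02, seed = 1) {
  if (is.null(schedule))
    schedule <- titration_data(heats = numeric(18))
  q <- wiseman_heats(kd, dh, n, schedule)
  qmax <- max(abs(q))
  heats <- with_seed(seed, {
    offset <- stats::rnorm(1, 0, offset_sd * qmax)
    q + offset + stats::rnorm(length(q), 0, noise_sd * qmax)
  })
  data <- schedule
  data$heats <- heats
  list(data = data,
       truth = truth_record(list(kd = kd, dh = dh, n = n), seed,
                            sprintf("gaussian sd = %g x max|heat| + constant offset (sd %g)",
                                    noise_sd, offset_sd)))
}

#' Simulate an MST dose-response
#'
#' Sixteen-point 1:1 dilution series from `top` (default 5 mM) mixed with
#' `receptor` (default 10 nM) labelled protein; responses follow
#' `baseline + amplitude * fraction_bound` with Gaussian noise of sd =
#' `noise_sd` x |amplitude|.
#'
#' @param kd generating dissociation constant, mol/L.
#' @param top highest ligand concentration, mol/L (default 5e-3).
#' @param n_points dilution steps (default 16).
#' @param receptor receptor concentration, mol/L (default 10e-9).
#' @param baseline,amplitude response model defaults (per mil).
#' @param noise_sd noise fraction of the amplitude (default 0.02).
#' @param seed integer seed.
#' @return list with `data` (a `dose_response`) and `truth`.
#' @export
simulate_mst <- function(kd, top = 5e-3, n_points = 16, receptor = 10e-9,
                         baseline = 850, amplitude = 25, noise_sd = 0.02,
                         seed = 1) {
  concs <- top / 2^(0:(n_points - 1))
  fb <- mst_fraction_bound(concs, receptor, kd)
  responses <- with_seed(seed,
    baseline + amplitude * fb +
      stats::rnorm(n_points, 0, noise_sd * abs(amplitude)))
  list(data = dose_response(concs, responses, receptor),
       truth = truth_record(list(kd = kd, baseline = baseline,
                                 amplitude = amplitude), seed,
                            sprintf("gaussian sd = %g x |amplitude|", noise_sd)))
}

# all proton-proton pairs of an ensemble's topology with their effective
# distances
proton_pair_distances <- function(ensemble) {
  topo <- ensemble$topology
  hs <- topo$atoms$id[topo$atoms$element == "H"]
  pairs <- utils::combn(hs, 2)
  reff <- apply(pairs, 2, function(p) ensemble_noe_distance(ensemble, p))
  data.frame(atom1 = pairs[1, ], atom2 = pairs[2, ], reff = reff,
             stringsAsFactors = FALSE)
}

# the nine scalar-coupling pathways of the opened reducing terminus
J_PATHWAYS <- list(
  c("T4 H1A", "T4 C1", "T4 C2", "T4 H2"),
  c("T4 H1B", "T4 C1", "T4 C2", "T4 H2"),
  c("T4 H2", "T4 C2", "T4 C3", "T4 H3"),
  c("T4 H3", "T4 C3", "T4 C4", "T4 H4"),
  c("T4 H4", "T4 C4", "T4 C5", "T4 H5"),
  c("T4 H5", "T4 C5", "T4 C6", "T4 H6A"),
  c("T4 H5", "T4 C5", "T4 C6", "T4 H6B"),
  c("X5 HN11", "X5 N11", "T4 C1", "T4 H1A"),
  c("X5 HN11", "X5 N11", "T4 C1", "T4 H1B"))

#' Forward-simulate a restraint set from an ensemble
#'
#' NOE upper bounds are `r_eff * (1 + slack)` for the closest
#' proton-proton pairs; noNOE lower bounds are `r_eff * (1 - slack)` for
#' the most distant pairs; scalar couplings are ensemble Karplus values of
#' the opened-chain pathways plus Gaussian noise; one aniline
#' temperature-coefficient record and one internal hydrogen-bond record
#' are included as annotations carrying the donor/acceptor pair. With
#' `total` set, NOE/noNOE counts are scaled so the set has exactly that
#' many restraints.
#'
#' @param ensemble a `glyco_ensemble` (with explicit protons).
#' @param n_noe,n_nonoe numbers of NOE / noNOE records (defaults 20 / 10).
#' @param total optional total restraint count to hit exactly.
#' @param j_noise_sd Gaussian sd on coupling targets, Hz (default 0).
#' @param j_tol scalar-coupling tolerance, Hz (default 0.5).
#' @param slack fractional slack on NOE/noNOE bounds (default 0).
#' @param noe_max eligible NOE pairs have `r_eff` at or below this (A).
#' @param nonoe_min eligible noNOE pairs have `r_eff` at or above this (A).
#' @param coeffs Karplus coefficients.
#' @param seed integer seed (noise draws only).
#' @return list with `set` (a `restraint_set`) and `truth`.
#' @export
simulate_restraints <- function(ensemble, n_noe = 20, n_nonoe = 10,
                                total = NULL, j_noise_sd = 0, j_tol = 0.5,
                                slack = 0, noe_max = 4.0, nonoe_min = 5.5,
                                coeffs = c(9.5, -1.6, 1.8), seed = 1,
                                model = NULL) {
  pd <- proton_pair_distances(ensemble)
  nj <- length(J_PATHWAYS)
  if (!is.null(total)) {
    n_fixed <- nj + 2L
    if (total < n_fixed + 2L) stop("total too small")
    n_noe <- ceiling((total - n_fixed) * 2 / 3)
    n_nonoe <- total - n_fixed - n_noe
  }
  close_pairs <- pd[pd$reff <= noe_max, ]
  close_pairs <- close_pairs[order(close_pairs$reff), ]
  far_pairs <- pd[pd$reff >= nonoe_min, ]
  far_pairs <- far_pairs[order(-far_pairs$reff), ]
  if (nrow(close_pairs) < n_noe || nrow(far_pairs) < n_nonoe)
    stop(sprintf("insufficient eligible pairs (%d close, %d far)",
                 nrow(close_pairs), nrow(far_pairs)))
  noe <- close_pairs[seq_len(n_noe), ]
  nonoe <- far_pairs[seq_len(n_nonoe), ]

  # coupling targets: finite-ensemble averages by default; with the
  # generating model supplied, the exact population-weighted expectations
  jvals <- if (is.null(model)) {
    vapply(J_PATHWAYS, function(p) ensemble_karplus(ensemble, p, coeffs), 0)
  } else {
    ref <- ensemble$conformers[[1]]
    vapply(J_PATHWAYS, function(p) {
      po <- pathway_torsion_offset(ensemble$topology, p, ref$xyz,
                                   ref$torsions)
      if (is.null(po)) return(ensemble_karplus(ensemble, p, coeffs))
      tn <- po$torsion
      if (tn %in% names(model$unimodal)) {
        md <- model$unimodal[[tn]]
        return(expected_mode_coupling(md$mu, md$sigma, po$offset, coeffs))
      }
      for (g in model$groups) {
        if (tn %in% g$torsions) {
          ek <- vapply(g$modes, function(mo)
            expected_mode_coupling(mo[[tn]]$mu, mo[[tn]]$sigma, po$offset,
                                   coeffs), 0)
          return(sum(g$populations * ek))
        }
      }
      ensemble_karplus(ensemble, p, coeffs)
    }, 0)
  }
  jvals <- with_seed(seed, jvals + stats::rnorm(nj, 0, j_noise_sd))

  df <- rbind(
    data.frame(kind = rep("NOE", nrow(noe)), atom1 = noe$atom1,
               atom2 = noe$atom2, bound = noe$reff * (1 + slack),
               tolerance = rep(NA_real_, nrow(noe)),
               note = rep("", nrow(noe)), stringsAsFactors = FALSE),
    data.frame(kind = rep("noNOE", nrow(nonoe)), atom1 = nonoe$atom1,
               atom2 = nonoe$atom2, bound = nonoe$reff * (1 - slack),
               tolerance = rep(NA_real_, nrow(nonoe)),
               note = rep("", nrow(nonoe)), stringsAsFactors = FALSE),
    data.frame(kind = "scalar3J",
               atom1 = vapply(J_PATHWAYS, `[[`, "", 1),
               atom2 = vapply(J_PATHWAYS, `[[`, "", 4),
               bound = jvals, tolerance = j_tol,
               note = vapply(J_PATHWAYS, paste, "", collapse = "|"),
               stringsAsFactors = FALSE),
    data.frame(kind = "tempCoeff", atom1 = "X5 N11", atom2 = "X5 O7A",
               bound = -2.6, tolerance = NA_real_,
               note = "aniline proton temperature coefficient, ppb/K",
               stringsAsFactors = FALSE),
    data.frame(kind = "hbond", atom1 = "X5 N11", atom2 = "X5 O7A",
               bound = 3.5, tolerance = NA_real_,
               note = "internal hydrogen bond of the aminobenzoate",
               stringsAsFactors = FALSE))
  list(set = restraint_set(df),
       truth = truth_record(
         list(model_hash = ensemble$model_hash, seed_ensemble = ensemble$seed,
              n_noe = n_noe, n_nonoe = n_nonoe, slack = slack,
              j_noise_sd = j_noise_sd), seed,
         sprintf("gaussian sd = %g Hz on couplings; slack %g on bounds",
                 j_noise_sd, slack)))
}

#' Deterministic binding-groove pocket fixture
#'
#' The `"link_tsg6_groove"` preset builds a surrogate of the Link-module
#' HA-binding groove around the mode-2 centroid conformer of the supplied
#' HA6-2AA topology: a cation site (arginine surrogate) placed at the
#' hydrogen-bond optimum from the mode-2 carboxylate position, an aromatic
#' shelf (tyrosine surrogate) and three hydrophobic spheres
#' (valine/glycine/isoleucine surrogates) framing the aminobenzoate ring,
#' and a steric wall behind the cation site. The anchor reference is the
#' centroid conformer's own anchor, so the pocket geometry guarantees that
#' mode-2-like reducing-terminal geometry reaches the cation site
#' (salt-bridge distance at or below 4 A).
#'
#' @param preset pocket preset name; only `"link_tsg6_groove"`.
#' @param topology the ligand `glyco_topology` (default HA6-2AA).
#' @param model the `dynamic_model` (default [ha4_2aa_model()]).
#' @return list with `pocket` (a `binding_pocket`) and `truth`.
#' @export
make_pocket_fixture <- function(preset = "link_tsg6_groove",
                                topology = NULL, model = NULL) {
  if (preset != "link_tsg6_groove") stop("unknown pocket preset: ", preset)
  if (is.null(topology)) topology <- ha_topology(6, "2AA")
  if (is.null(model)) model <- ha4_2aa_model()

  # mode-2 centroid: unimodal means plus the mode-2 means of the group
  tv <- vapply(model$unimodal, `[[`, 0, "mu")
  g <- model$groups[[1]]
  for (tn in g$torsions) tv[tn] <- g$modes[[2]][[tn]]$mu
  xyz <- build_cartesian(topology, tv)

  o7a <- xyz["X5 O7A", ]; c13 <- xyz["X5 C13", ]
  u <- (o7a - c13) / sqrt(sum((o7a - c13)^2))
  cation <- o7a + 2.9 * u

  ring <- xyz[topology$aromatic_carbons, ]
  centroid <- colMeans(ring)
  nrm <- cross3(ring[2, ] - ring[1, ], ring[3, ] - ring[1, ])
  nrm <- nrm / sqrt(sum(nrm^2))
  in_plane <- (ring[4, ] - centroid) / sqrt(sum((ring[4, ] - centroid)^2))

  sites <- rbind(
    data.frame(label = "Arg81-NH1", role = "cation",
               x = cation[1], y = cation[2], z = cation[3], radius = 1.8),
    data.frame(label = "Tyr78-ring", role = "aromatic",
               x = centroid[1] + 3.8 * nrm[1], y = centroid[2] + 3.8 * nrm[2],
               z = centroid[3] + 3.8 * nrm[3], radius = 2.2),
    data.frame(label = "Val57", role = "hydrophobic",
               x = centroid[1] - 4.2 * nrm[1], y = centroid[2] - 4.2 * nrm[2],
               z = centroid[3] - 4.2 * nrm[3], radius = 2.0),
    data.frame(label = "Gly79", role = "hydrophobic",
               x = centroid[1] + 4.5 * in_plane[1],
               y = centroid[2] + 4.5 * in_plane[2],
               z = centroid[3] + 4.5 * in_plane[3], radius = 1.7),
    data.frame(label = "Ile80", role = "hydrophobic",
               x = centroid[1] + 3.2 * nrm[1] + 3.2 * in_plane[1],
               y = centroid[2] + 3.2 * nrm[2] + 3.2 * in_plane[2],
               z = centroid[3] + 3.2 * nrm[3] + 3.2 * in_plane[3],
               radius = 2.0),
    data.frame(label = "groove-wall", role = "steric",
               x = cation[1] + 4.0 * u[1], y = cation[2] + 4.0 * u[2],
               z = cation[3] + 4.0 * u[3], radius = 2.5))

  pocket <- binding_pocket(sites, xyz[topology$anchor, , drop = FALSE])
  list(pocket = pocket,
       truth = truth_record(
         list(preset = preset, centroid_mode = 2,
              cation_distance = 2.9,
              n_residues = topology$n_residues), seed = 0L,
         "deterministic (no randomness)"))
}
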