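# Back-calculation of NMR observables from conformer ensembles and
# restraint-based validation.

#' Karplus three-bond coupling
#'
#' `J = A cos^2(theta) + B cos(theta) + C`. The default coefficients
#' (A = 9.5, B = -1.6, C = 1.8 Hz) are a standard HCCH parameterisation;
#' they are configurable because Karplus curves are re-parameterised per
#' coupling pathway.
#'
#' @param theta dihedral angle(s), degrees.
#' @param coeffs numeric `(A, B, C)` in Hz.
#' @return coupling constant(s) in Hz.
#' @export
karplus_3j <- function(theta, coeffs = c(9.5, -1.6, 1.8)) {
  ct <- cos(theta * pi / 180)
  coeffs[1] * ct^2 + coeffs[2] * ct + coeffs[3]
}

#' Ensemble-averaged Karplus coupling
#'
#' Averages the pointwise Karplus value of a proton-proton dihedral over
#' the conformers of an ensemble (couplings average linearly on the NMR
#' chemical-shift timescale).
#'
#' @param ensemble a `glyco_ensemble`.
#' @param atoms four atom identifiers (H, C, C, H) defining the dihedral.
#' @param coeffs Karplus coefficients, see [karplus_3j()].
#' @param weights optional per-conformer weights (sum to 1); uniform by
#'   default (conformers are already drawn from the mode occupancies).
#' @return ensemble coupling in Hz.
#' @export
ensemble_karplus <- function(ensemble, atoms, coeffs = c(9.5, -1.6, 1.8),
                             weights = NULL) {
  th <- vapply(ensemble$conformers,
               function(cf) measure_torsion(cf$xyz, atoms), 0)
  w <- normalise_weights(weights, length(th))
  sum(w * karplus_3j(th, coeffs))
}

normalise_weights <- function(weights, n) {
  if (is.null(weights)) return(rep(1 / n, n))
  if (length(weights) != n) stop("need one weight per conformer")
  if (any(weights < 0)) stop("negative weight")
  s <- sum(weights)
  if (abs(s - 1) > 1e-6) stop("weights must sum to 1")
  weights / s
}

#' Effective NOE distance by r^-6 ensemble averaging
#'
#' `r_eff = (sum_i w_i r_i^-6)^(-1/6)`; short distances dominate, as in
#' NOE cross-relaxation.
#'
#' @param ensemble a `glyco_ensemble`.
#' @param atoms pair of atom identifiers.
#' @param weights optional per-conformer weights (sum to 1; uniform
#'   default).
#' @return effective distance in Angstrom.
#' @export
ensemble_noe_distance <- function(ensemble, atoms, weights = NULL) {
  stopifnot(length(atoms) == 2L)
  r <- vapply(ensemble$conformers, function(cf) {
    d <- sqrt(sum((cf$xyz[atoms[1], ] - cf$xyz[atoms[2], ])^2))
    if (d < 1e-8) stop("zero interatomic distance in a conformer")
    d
  }, 0)
  w <- normalise_weights(weights, length(r))
  sum(w * r^-6)^(-1 / 6)
}

# ---- restraint sets ------------------------------------------------------

RESTRAINT_KINDS <- c("NOE", "noNOE", "scalar3J", "tempCoeff", "hbond")

#' Construct a restraint set
#'
#' @param df data.frame with columns `kind` (one of NOE, noNOE, scalar3J,
#'   tempCoeff, hbond), `atom1`, `atom2` (NA where not applicable),
#'   `bound` (upper distance A for NOE, lower distance A for noNOE, target
#'   coupling Hz for scalar3J, coefficient ppb/K for tempCoeff),
#'   `tolerance` (Hz, scalar3J only) and `note`.
#' @return an object of class `restraint_set`.
#' @export
restraint_set <- function(df) {
  need <- c("kind", "atom1", "atom2", "bound", "tolerance", "note")
  for (cn in setdiff(need, names(df))) df[[cn]] <- NA
  df <- df[, need]
  if (!all(df$kind %in% RESTRAINT_KINDS))
    stop("unknown restraint kind(s): ",
         paste(setdiff(df$kind, RESTRAINT_KINDS), collapse = ", "))
  dist_kind <- df$kind %in% c("NOE", "noNOE")
  if (any(dist_kind & (!is.finite(df$bound) | df$bound <= 0)))
    stop("NOE/noNOE bounds must be positive")
  j <- df$kind == "scalar3J"
  if (any(j & (!is.finite(df$tolerance) | df$tolerance <= 0)))
    stop("scalar3J restraints need a positive tolerance")
  structure(list(restraints = df), class = "restraint_set")
}

#' Number of restraints
#' @param set a `restraint_set`.
#' @return integer count.
#' @export
restraint_count <- function(set) nrow(set$restraints)

#' @export
print.restraint_set <- function(x, ...) {
  cat("Restraint set:", restraint_count(x), "restraints\n")
  print(table(x$restraints$kind))
  invisible(x)
}

#' Read restraints from CSV
#'
#' Columns `kind, atom1, atom2, bound, tolerance, note`.
#' @param path CSV file path.
#' @return a `restraint_set`.
#' @export
read_restraints <- function(path)
  restraint_set(utils::read.csv(path, stringsAsFactors = FALSE))

#' Write restraints to CSV
#' @param set a `restraint_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_restraints <- function(set, path) {
  utils::write.csv(set$restraints, path, row.names = FALSE)
  invisible(path)
}

# the hydrogen bonded to a donor heavy atom, if the topology carries one
find_donor_hydrogen <- function(topology, donor) {
  b <- topology$bonds
  cand <- c(b$a1[b$a2 == donor], b$a2[b$a1 == donor])
  h <- cand[vapply(cand, element_of, "") == "H"]
  if (length(h) == 0L) NA_character_ else h[1]
}

#' Check restraint satisfaction against an ensemble
#'
#' NOE: satisfied iff the r^-6 effective distance is at or below the upper
#' bound. noNOE: satisfied iff it is at or above the lower bound.
#' scalar3J: satisfied iff the ensemble coupling is within tolerance of the
#' target. hbond (and tempCoeff records carrying a donor/acceptor pair) are
#' checked geometrically: donor-acceptor heavy-atom distance <= 3.5 A and,
#' when an explicit donor hydrogen exists, donor-H...acceptor angle >= 120
#' degrees, in at least half of the conformers. tempCoeff records without
#' an acceptor are provenance annotations and always report satisfied with
#' zero margin.
#'
#' @param ensemble a `glyco_ensemble`.
#' @param set a `restraint_set`.
#' @param coeffs Karplus coefficients for scalar3J back-calculation.
#' @param hbond_dist,hbond_angle,hbond_fraction geometric hydrogen-bond
#'   criterion (A, degrees, fraction of conformers).
#' @return a `restraint_report`: data.frame with per-restraint `kind`,
#'   `observed`, `bound`, `satisfied`, `margin` (positive = satisfied by
#'   that amount) plus summary attributes.
#' @export
check_restraints <- function(ensemble, set, coeffs = c(9.5, -1.6, 1.8),
                             hbond_dist = 3.5, hbond_angle = 120,
                             hbond_fraction = 0.5) {
  df <- set$restraints
  n <- nrow(df)
  observed <- numeric(n)
  satisfied <- logical(n)
  margin <- numeric(n)
  topo <- ensemble$topology
  for (i in seq_len(n)) {
    kind <- df$kind[i]
    if (kind == "NOE") {
      r <- ensemble_noe_distance(ensemble, c(df$atom1[i], df$atom2[i]))
      observed[i] <- r
      margin[i] <- df$bound[i] - r
      satisfied[i] <- r <= df$bound[i] + 1e-9
    } else if (kind == "noNOE") {
      r <- ensemble_noe_distance(ensemble, c(df$atom1[i], df$atom2[i]))
      observed[i] <- r
      margin[i] <- r - df$bound[i]
      satisfied[i] <- r >= df$bound[i] - 1e-9
    } else if (kind == "scalar3J") {
      atoms <- strsplit(df$note[i], "\\|")[[1]]
      if (length(atoms) != 4L)
        stop("scalar3J restraints carry the dihedral quadruple in the note ",
             "field as 'a|b|c|d'")
      jv <- ensemble_karplus(ensemble, atoms, coeffs)
      observed[i] <- jv
      margin[i] <- df$tolerance[i] - abs(jv - df$bound[i])
      satisfied[i] <- abs(jv - df$bound[i]) <= df$tolerance[i] + 1e-9
    } else if (kind == "hbond" ||
               (kind == "tempCoeff" && !is.na(df$atom2[i]))) {
      donor <- df$atom1[i]; acceptor <- df$atom2[i]
      h <- find_donor_hydrogen(topo, donor)
      ok <- vapply(ensemble$conformers, function(cf) {
        d <- sqrt(sum((cf$xyz[donor, ] - cf$xyz[acceptor, ])^2))
        if (d > hbond_dist) return(FALSE)
        if (is.na(h)) return(TRUE)
        v <- cf$xyz[donor, ] - cf$xyz[h, ]
        w <- cf$xyz[acceptor, ] - cf$xyz[h, ]
        ang <- acos(sum(v * w) / sqrt(sum(v^2) * sum(w^2))) * 180 / pi
        ang >= hbond_angle
      }, TRUE)
      observed[i] <- mean(ok)
      margin[i] <- mean(ok) - hbond_fraction
      satisfied[i] <- mean(ok) >= hbond_fraction
    } else {                        # tempCoeff annotation
      observed[i] <- df$bound[i]
      margin[i] <- 0
      satisfied[i] <- TRUE
    }
  }
  rep <- data.frame(kind = df$kind, atom1 = df$atom1, atom2 = df$atom2,
                    bound = df$bound, observed = observed,
                    satisfied = satisfied, margin = margin)
  structure(rep, class = c("restraint_report", "data.frame"),
            n_satisfied = sum(satisfied), n_total = n)
}

#' @export
print.restraint_report <- function(x, ...) {
  cat(sprintf("Restraint report: %d/%d satisfied\n",
              attr(x, "n_satisfied"), attr(x, "n_total")))
  NextMethod()
}

# ---- mode-population recovery -------------------------------------------

# all compositions of total `steps` into `k` parts, as a (rows x k) matrix
# of fractions; deterministic lexicographic order
simplex_grid <- function(k, resolution) {
  steps <- round(1 / resolution)
  rec <- function(k, s) {
    if (k == 1L) return(matrix(s, 1, 1))
    out <- vector("list", s + 1L)
    for (i in 0:s) out[[i + 1L]] <- cbind(i, rec(k - 1L, s - i))
    do.call(rbind, out)
  }
  rec(k, steps) / steps
}

#' Expected Karplus coupling over a wrapped-normal libration
#'
#' `E[J]` for a dihedral `theta = t + offset` with `t` wrapped-normal
#' (`mu`, `sigma`); evaluated by dense trapezoidal quadrature over +-5
#' sigma (exact to numerical precision for the smooth Karplus curve).
#'
#' @param mu,sigma libration mean and width, degrees.
#' @param offset fixed pathway offset, degrees.
#' @param coeffs Karplus coefficients.
#' @return expected coupling, Hz.
#' @export
expected_mode_coupling <- function(mu, sigma, offset = 0,
                                   coeffs = c(9.5, -1.6, 1.8)) {
  t <- seq(mu - 5 * sigma, mu + 5 * sigma, length.out = 201)
  w <- stats::dnorm(t, mu, sigma)
  w <- w / sum(w)
  sum(w * karplus_3j(t + offset, coeffs))
}

# the free torsion whose central bond matches a dihedral pathway, plus the
# fixed pathway offset, measured on one reference conformation
pathway_torsion_offset <- function(topology, pathway, ref_xyz, ref_torsions) {
  central <- sort(pathway[2:3])
  for (tn in names(topology$torsion_atoms)) {
    q <- topology$torsion_atoms[[tn]]
    if (identical(sort(q[2:3]), central)) {
      off <- wrap_angle(measure_torsion(ref_xyz, pathway) - ref_torsions[[tn]])
      return(list(torsion = tn, offset = off))
    }
  }
  NULL
}

# per-mode observable matrix for the restraints that inform populations:
# scalar3J rows are linear in pi (J averages linearly) and are computed
# analytically from the mode parameters where the pathway rides a group
# torsion; NOE/noNOE rows are linear in pi on the r^-6 scale and come from
# the single-mode ensembles.
mode_observable_matrix <- function(set, mode_ensembles, model, group,
                                   coeffs = c(9.5, -1.6, 1.8)) {
  df <- set$restraints
  keep <- which(df$kind %in% c("scalar3J", "NOE", "noNOE"))
  K <- length(mode_ensembles)
  topo <- mode_ensembles[[1]]$topology
  ref <- mode_ensembles[[1]]$conformers[[1]]
  O <- matrix(NA_real_, length(keep), K)
  for (r in seq_along(keep)) {
    i <- keep[r]
    if (df$kind[i] == "scalar3J") {
      atoms <- strsplit(df$note[i], "\\|")[[1]]
      po <- pathway_torsion_offset(topo, atoms, ref$xyz, ref$torsions)
      if (!is.null(po) && po$torsion %in% group$torsions) {
        for (k in seq_len(K)) {
          md <- group$modes[[k]][[po$torsion]]
          O[r, k] <- expected_mode_coupling(md$mu, md$sigma, po$offset, coeffs)
        }
      } else if (!is.null(po) && po$torsion %in% names(model$unimodal)) {
        md <- model$unimodal[[po$torsion]]
        O[r, ] <- expected_mode_coupling(md$mu, md$sigma, po$offset, coeffs)
      } else {
        for (k in seq_len(K))
          O[r, k] <- ensemble_karplus(mode_ensembles[[k]], atoms, coeffs)
      }
    } else {
      for (k in seq_len(K))
        O[r, k] <- ensemble_noe_distance(mode_ensembles[[k]],
                                         c(df$atom1[i], df$atom2[i]))^-6
    }
  }
  list(O = O, rows = keep)
}

population_objective <- function(P, O, df, rows) {
  # P: (m x K) candidate populations; returns vector of objectives
  pred <- P %*% t(O)                      # m x n_restraints
  obj <- numeric(nrow(P))
  for (r in seq_along(rows)) {
    i <- rows[r]
    if (df$kind[i] == "scalar3J") {
      obj <- obj + (pred[, r] - df$bound[i])^2
    } else if (df$kind[i] == "NOE") {
      reff <- pred[, r]^(-1 / 6)
      obj <- obj + pmax(0, reff - df$bound[i])^2
    } else {                              # noNOE
      reff <- pred[, r]^(-1 / 6)
      obj <- obj + pmax(0, df$bound[i] - reff)^2
    }
  }
  obj
}

#' Recover mode populations from restraints
#'
#' Grid search on the probability simplex for the occupancy vector of a
#' codependent group that best reproduces population-sensitive observables
#' (ensemble scalar couplings exactly, NOE/noNOE bounds as one-sided
#' violations). Per-mode observables are computed once from single-mode
#' ensembles; couplings and r^-6 intensities average linearly in the
#' occupancies, so the objective is evaluated exactly on every grid point.
#' A full enumeration at `coarse` resolution seeds a deterministic local
#' pairwise-transfer descent at resolution `grid` (the objective is convex
#' in the occupancies, so the descent reaches the grid optimum); ties break
#' toward the uniform distribution.
#'
#' @param set a `restraint_set` simulated from / measured on the system.
#' @param model a `dynamic_model` whose group `group_id` has unknown
#'   occupancies (its stated occupancies are ignored).
#' @param topology the `glyco_topology` the restraint atoms live in.
#' @param group_id codependent group to fit; default first group.
#' @param grid target grid resolution for the occupancies (default 0.01).
#' @param coarse resolution of the exhaustive stage (default 0.05).
#' @param n_per_mode conformers per single-mode ensemble (default 400).
#' @param seed seed for the single-mode ensembles.
#' @param coeffs Karplus coefficients.
#' @return list with `populations` (recovered occupancies), `objective`
#'   (value at the optimum), `trace` (data.frame of the descent path) and
#'   `mode_ensembles` problem size.
#' @export
fit_mode_populations <- function(set, model, topology, group_id = NULL,
                                 grid = 0.01, coarse = 0.05,
                                 n_per_mode = 400, seed = 1,
                                 coeffs = c(9.5, -1.6, 1.8)) {
  ids <- vapply(model$groups, `[[`, "", "id")
  if (is.null(group_id)) group_id <- ids[1]
  gi <- match(group_id, ids)
  if (is.na(gi)) stop("unknown group id: ", group_id)
  g <- model$groups[[gi]]
  K <- length(g$modes)
  if (K == 1L)
    return(list(populations = 1, objective = 0,
                trace = data.frame(), n_modes = 1L))

  # single-mode ensembles: pin the group to one mode, keep everything else
  mode_ensembles <- lapply(seq_len(K), function(k) {
    gk <- g; gk$modes <- g$modes[k]; gk$populations <- 1
    mk <- model; mk$groups[[gi]] <- gk
    generate_ensemble(mk, topology, n = n_per_mode, seed = seed + k)
  })
  mo <- mode_observable_matrix(set, mode_ensembles, model, g, coeffs)
  if (nrow(mo$O) == 0L)
    stop("no population-sensitive restraints (need scalar3J / NOE / noNOE)")
  df <- set$restraints

  uniform <- rep(1 / K, K)
  score <- function(P) population_objective(P, mo$O, df, mo$rows)
  # stage 1: exhaustive coarse enumeration
  Pc <- simplex_grid(K, coarse)
  oc <- score(Pc)
  best_i <- which(oc <= min(oc) + 1e-15)
  if (length(best_i) > 1L) {   # ties toward uniform
    dunif <- rowSums((Pc[best_i, , drop = FALSE] -
                        matrix(uniform, length(best_i), K, byrow = TRUE))^2)
    best_i <- best_i[which.min(dunif)]
  }
  p <- Pc[best_i[1], ]
  obj <- score(matrix(p, 1))
  trace <- data.frame(stage = "coarse", objective = obj)

  # stage 2: exact constrained least squares on the coupling rows (they
  # are linear in pi), enumerating active sets of zeroed modes; among
  # exact minimisers the solution closest to uniform is taken, then the
  # candidate is snapped to the fine grid by largest-remainder rounding
  jrows <- which(df$kind[mo$rows] == "scalar3J")
  if (length(jrows) > 0L) {
    A <- mo$O[jrows, , drop = FALSE]
    bvec <- df$bound[mo$rows[jrows]]
    best_cand <- NULL
    for (mask in 0:(2^K - 2)) {
      zero <- which(bitwAnd(mask, 2^(seq_len(K) - 1)) > 0)
      free <- setdiff(seq_len(K), zero)
      if (length(free) == 0L) next
      Af <- A[, free, drop = FALSE]
      p0 <- rep(1 / length(free), length(free))
      pc_full <- rep(0, K)
      if (length(free) == 1L) {
        pc_full[free] <- 1
      } else {
        Z <- qr.Q(qr(matrix(1, length(free), 1)), complete = TRUE)[, -1,
                                                                   drop = FALSE]
        M <- Af %*% Z
        sv <- svd(M)
        pos <- sv$d > max(sv$d[1], 1e-12) * 1e-10
        y <- sv$v[, pos, drop = FALSE] %*%
          ((t(sv$u[, pos, drop = FALSE]) %*% (bvec - Af %*% p0)) / sv$d[pos])
        pc_full[free] <- p0 + as.vector(Z %*% y)
      }
      if (any(pc_full < -1e-9)) next
      pc_full <- pmax(pc_full, 0)
      pc_full <- pc_full / sum(pc_full)
      o <- score(matrix(pc_full, 1))
      if (is.null(best_cand) || o < best_cand$obj - 1e-15 ||
          (o < best_cand$obj + 1e-15 &&
           sum((pc_full - uniform)^2) < sum((best_cand$p - uniform)^2)))
        best_cand <- list(p = pc_full, obj = o)
    }
    if (!is.null(best_cand)) {
      steps <- round(1 / grid)
      base <- floor(best_cand$p * steps)
      rem <- best_cand$p * steps - base
      short <- steps - sum(base)
      if (short > 0)
        base[order(-rem)[seq_len(short)]] <-
          base[order(-rem)[seq_len(short)]] + 1
      p_snap <- base / steps
      if (score(matrix(p_snap, 1)) <= obj + 1e-15) {
        p <- p_snap
        obj <- score(matrix(p, 1))
      }
    }
    trace <- rbind(trace, data.frame(stage = "lsq", objective = obj))
  }

  # stage 3: pairwise mass transfers at the fine resolution
  h <- grid
  repeat {
    moves <- list()
    for (a in seq_len(K)) for (b in seq_len(K)) {
      if (a != b && p[a] >= h - 1e-12) {
        q <- p; q[a] <- q[a] - h; q[b] <- q[b] + h
        moves[[length(moves) + 1L]] <- q
      }
    }
    Pm <- do.call(rbind, moves)
    om <- score(Pm)
    if (min(om) < obj - 1e-15) {
      cand <- which(om <= min(om) + 1e-15)
      if (length(cand) > 1L) {
        dunif <- rowSums((Pm[cand, , drop = FALSE] -
                            matrix(uniform, length(cand), K, byrow = TRUE))^2)
        cand <- cand[which.min(dunif)]
      }
      p <- Pm[cand[1], ]
      obj <- min(om)
      trace <- rbind(trace, data.frame(stage = "refine", objective = obj))
    } else break
  }
  list(populations = round(p / sum(p), 10), objective = obj,
       trace = trace, n_modes = K)
}
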