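# Rigid-body anchored placement into a binding-groove pocket and
# component scoring (hydrogen bonding, van der Waals, ligand torsion
# strain), with salt-bridge detection and per-mode score summaries.
#
# Scores are in arbitrary energy-like units; only orderings and groupings
# are meaningful. "Favorability" is the negated energy, so higher values
# represent more favourable interactions.

POCKET_ROLES <- c("hbond_donor", "hbond_acceptor", "cation", "aromatic",
                  "hydrophobic", "steric")

#' Construct a binding-groove pocket
#'
#' A pocket is a set of pseudo-atom interaction sites plus the reference
#' coordinates the ligand anchor is superposed onto.
#'
#' @param sites data.frame with columns `label` (unique), `role` (one of
#'   hbond_donor, hbond_acceptor, cation, aromatic, hydrophobic, steric),
#'   `x`, `y`, `z` (A) and `radius` (A).
#' @param anchor_reference numeric matrix (>= 3 non-collinear rows) of
#'   target coordinates, rownames = ligand anchor atom identifiers.
#' @return an object of class `binding_pocket`.
#' @export
binding_pocket <- function(sites, anchor_reference) {
  need <- c("label", "role", "x", "y", "z", "radius")
  stopifnot(all(need %in% names(sites)))
  if (!all(sites$role %in% POCKET_ROLES))
    stop("unknown site role(s): ",
         paste(setdiff(sites$role, POCKET_ROLES), collapse = ", "))
  if (anyDuplicated(sites$label)) stop("site labels must be unique")
  if (!any(sites$role == "steric")) stop("pocket needs at least one steric site")
  anchor_reference <- as.matrix(anchor_reference)
  if (nrow(anchor_reference) < 3L || is.null(rownames(anchor_reference)))
    stop("anchor_reference needs >= 3 named rows")
  structure(list(sites = sites, anchor_reference = anchor_reference),
            class = "binding_pocket")
}

#' @export
print.binding_pocket <- function(x, ...) {
  cat("Binding pocket:", nrow(x$sites), "sites (",
      paste(sprintf("%s:%d", names(table(x$sites$role)),
                    as.integer(table(x$sites$role))), collapse = ", "),
      "),", nrow(x$anchor_reference), "anchor reference atoms\n")
  invisible(x)
}

#' Superpose a conformer's anchor onto the pocket reference
#'
#' Least-squares rigid fit (proper rotation + translation, no scaling) of
#' the ligand anchor atoms onto `pocket$anchor_reference`; the whole
#' conformer is moved by the fitted transform.
#'
#' @param conformer a conformer (list with `xyz`) or a bare coordinate
#'   matrix with named rows.
#' @param pocket a `binding_pocket`.
#' @return list with `xyz` (transformed coordinates), `rmsd` (anchor RMSD
#'   after the fit) and the fit `rotation` / `translation`.
#' @export
superpose_anchor <- function(conformer, pocket) {
  xyz <- if (is.list(conformer) && !is.null(conformer$xyz)) conformer$xyz
         else as.matrix(conformer)
  ref <- pocket$anchor_reference
  ids <- rownames(ref)
  if (!all(ids %in% rownames(xyz)))
    stop("conformer lacks anchor atom(s): ",
         paste(setdiff(ids, rownames(xyz)), collapse = ", "))
  fit <- kabsch_superpose(xyz[ids, , drop = FALSE], ref)
  list(xyz = fit$transform(xyz), rmsd = fit$rmsd,
       rotation = fit$rotation, translation = fit$translation)
}

# hydrogen-bond well: full depth at the optimum separation, quadratically
# damped to zero at the cutoff
hbond_well <- function(d, opt = 2.9, cutoff = 4.5, depth = 4.0) {
  f <- 1 - ((d - opt) / (cutoff - opt))^2
  -depth * pmax(0, f)
}

# soft 4-8 van der Waals well with a clash cap
vdw_48 <- function(d, r0, eps, cap = 10) {
  x <- (r0 / pmax(d, 1e-6))
  pmin(eps * (x^8 - 2 * x^4), cap)
}

#' Score a placed pose against a pocket
#'
#' Component energies: `hbond` sums a distance-damped well (optimum 2.9 A,
#' depth -4, zero beyond 4.5 A) over pocket donor/acceptor sites paired
#' with ligand polar atoms, and over cation sites paired with ligand
#' carboxylate oxygens (charge-assisted hydrogen bonds); `vdw` sums a soft
#' 4-8 potential of steric sites against all heavy atoms (clash-capped)
#' plus shallow attractive wells of aromatic/hydrophobic sites against
#' ligand aromatic carbons; `torsion_strain` sums `k (1 - cos(theta -
#' mu_nearest))` with k = 0.5 over the sampled torsions, `mu_nearest`
#' being the nearest mode mean in the dynamic model. `total` is their sum
#' and `favorability = -total` (higher is better).
#'
#' @param xyz placed ligand coordinates (rows named by atom id).
#' @param pocket a `binding_pocket`.
#' @param topology the ligand `glyco_topology` (atom roles).
#' @param torsion_values named torsion vector of the pose (degrees);
#'   optional, strain is 0 when absent.
#' @param model the `dynamic_model` supplying mode means for the strain
#'   term; optional with `torsion_values`.
#' @param strain_k torsion strain force constant (default 0.5).
#' @return an object of class `pose_score`: list with `hbond`, `vdw`,
#'   `torsion_strain`, `total`, `favorability`, `salt_bridge`,
#'   `min_no_dist`, `clashes`.
#' @export
score_pose <- function(xyz, pocket, topology, torsion_values = NULL,
                       model = NULL, strain_k = 0.5) {
  sites <- pocket$sites
  spos <- as.matrix(sites[, c("x", "y", "z")])
  els <- topology$atoms$element[match(rownames(xyz), topology$atoms$id)]
  heavy <- rownames(xyz)[els != "H"]
  polar <- rownames(xyz)[els %in% c("O", "N")]
  carbox <- intersect(topology$carboxylate_oxygens, rownames(xyz))
  arom <- intersect(topology$aromatic_carbons, rownames(xyz))

  dist_to <- function(ids, k) {
    if (length(ids) == 0L) return(numeric(0))
    sqrt(colSums((t(xyz[ids, , drop = FALSE]) - spos[k, ])^2))
  }

  hb <- 0; vdw <- 0; clashes <- 0L
  for (k in seq_len(nrow(sites))) {
    role <- sites$role[k]
    if (role %in% c("hbond_donor", "hbond_acceptor")) {
      hb <- hb + sum(hbond_well(dist_to(polar, k)))
    } else if (role == "cation") {
      hb <- hb + sum(hbond_well(dist_to(carbox, k)))
    } else if (role == "steric") {
      d <- dist_to(heavy, k)
      r0 <- sites$radius[k] + 1.7
      vdw <- vdw + sum(vdw_48(d, r0, eps = 0.2))
      clashes <- clashes + sum(d < 0.75 * r0)
    } else {                       # aromatic / hydrophobic
      d <- dist_to(arom, k)
      r0 <- sites$radius[k] + 1.7
      vdw <- vdw + sum(vdw_48(d, r0, eps = 0.5))
      clashes <- clashes + sum(d < 0.75 * r0)
    }
  }

  strain <- 0
  if (!is.null(torsion_values) && !is.null(model)) {
    for (nm in names(torsion_values)) {
      mus <- NULL
      if (nm %in% names(model$unimodal)) {
        mus <- model$unimodal[[nm]]$mu
      } else {
        for (g in model$groups)
          if (nm %in% g$torsions)
            mus <- vapply(g$modes, function(mo) mo[[nm]]$mu, 0)
      }
      if (is.null(mus)) next
      dev <- abs(wrap_angle(torsion_values[[nm]] - mus))
      strain <- strain + strain_k * (1 - cos(min(dev) * pi / 180))
    }
  }

  sb <- detect_salt_bridge(xyz, pocket, topology)
  total <- hb + vdw + strain
  structure(list(hbond = hb, vdw = vdw, torsion_strain = strain,
                 total = total, favorability = -total,
                 salt_bridge = sb$salt_bridge, min_no_dist = sb$min_no_dist,
                 clashes = clashes),
            class = "pose_score")
}

#' @export
print.pose_score <- function(x, ...) {
  cat(sprintf(
    "Pose score: favorability %.3f (hbond %.3f, vdw %.3f, strain %.3f); salt bridge: %s (min N-O %.2f A)\n",
    x$favorability, x$hbond, x$vdw, x$torsion_strain,
    if (isTRUE(x$salt_bridge)) "yes" else "no", x$min_no_dist))
  invisible(x)
}

#' Detect a carboxylate-cation salt bridge
#'
#' Flags a salt bridge when any ligand carboxylate oxygen lies within
#' `cutoff` (default 4.0 A, inclusive) of any cation site.
#'
#' @param xyz placed ligand coordinates.
#' @param pocket a `binding_pocket`.
#' @param topology ligand topology (identifies carboxylate oxygens).
#' @param cutoff distance criterion in A.
#' @return list with `salt_bridge` (logical), `min_no_dist` (A; `Inf` with
#'   a `note` when the ligand has no carboxylate or the pocket no cation).
#' @export
detect_salt_bridge <- function(xyz, pocket, topology, cutoff = 4.0) {
  cat_sites <- which(pocket$sites$role == "cation")
  carbox <- intersect(topology$carboxylate_oxygens, rownames(xyz))
  if (length(cat_sites) == 0L || length(carbox) == 0L)
    return(list(salt_bridge = FALSE, min_no_dist = Inf,
                note = "no carboxylate/cation pair available"))
  spos <- as.matrix(pocket$sites[cat_sites, c("x", "y", "z"), drop = FALSE])
  dmin <- Inf
  for (k in seq_len(nrow(spos)))
    dmin <- min(dmin, sqrt(colSums((t(xyz[carbox, , drop = FALSE]) -
                                      spos[k, ])^2)))
  list(salt_bridge = dmin <= cutoff, min_no_dist = dmin)
}

#' Dock and rank a whole ensemble
#'
#' Superposes every conformer's anchor into the pocket, scores it, and
#' ranks by favorability (descending; ties broken by conformer index).
#'
#' @param ensemble a `glyco_ensemble`.
#' @param pocket a `binding_pocket`.
#' @param model optional `dynamic_model` for the torsion-strain component.
#' @return an object of class `docking_result`: `scores` data.frame
#'   (conformer, mode, hbond, vdw, strain, total, favorability,
#'   salt_bridge, min_no_dist, clashes, anchor_rmsd, rank) and `summary`,
#'   the per-mode [mode_score_summary()].
#' @export
rank_ensemble <- function(ensemble, pocket, model = NULL) {
  n <- length(ensemble$conformers)
  modes <- ensemble_mode_labels(ensemble)
  if (is.null(modes)) modes <- rep(NA_integer_, n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    cf <- ensemble$conformers[[i]]
    sup <- superpose_anchor(cf, pocket)
    sc <- score_pose(sup$xyz, pocket, ensemble$topology,
                     torsion_values = cf$torsions, model = model)
    rows[[i]] <- data.frame(
      conformer = i, mode = modes[i], hbond = sc$hbond, vdw = sc$vdw,
      strain = sc$torsion_strain, total = sc$total,
      favorability = sc$favorability, salt_bridge = sc$salt_bridge,
      min_no_dist = sc$min_no_dist, clashes = sc$clashes,
      anchor_rmsd = sup$rmsd)
  }
  scores <- do.call(rbind, rows)
  ord <- order(-scores$favorability, scores$conformer)
  scores$rank <- NA_integer_
  scores$rank[ord] <- seq_len(n)
  structure(list(scores = scores, summary = mode_score_summary(scores)),
            class = "docking_result")
}

#' Per-mode score summary
#'
#' Mean, interquartile range, minimum and maximum favorability per mode
#' group (boxplot statistics), with per-mode counts summing to the
#' ensemble size.
#'
#' @param scores the `scores` data.frame of a [rank_ensemble()] result.
#' @return data.frame with one row per mode: `mode, n, mean, q1, q3, min,
#'   max`.
#' @export
mode_score_summary <- function(scores) {
  sp <- split(scores$favorability, scores$mode)
  out <- do.call(rbind, lapply(names(sp), function(m) {
    v <- sp[[m]]
    data.frame(mode = as.integer(m), n = length(v), mean = mean(v),
               q1 = unname(stats::quantile(v, 0.25)),
               q3 = unname(stats::quantile(v, 0.75)),
               min = min(v), max = max(v))
  }))
  out[order(out$mode), , drop = FALSE]
}

#' @export
print.docking_result <- function(x, ...) {
  top <- x$scores[x$scores$rank == 1, ]
  cat(sprintf(
    "Docking result: %d poses; top pose conformer %d (mode %s), favorability %.3f, salt bridge: %s\n",
    nrow(x$scores), top$conformer, top$mode, top$favorability,
    if (isTRUE(top$salt_bridge)) "yes" else "no"))
  cat("Per-mode favorability summary:\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write docking scores to CSV
#' @param result a `docking_result`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_scores_csv <- function(result, path) {
  utils::write.csv(result$scores, path, row.names = FALSE)
  invisible(path)
}
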