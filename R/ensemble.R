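# Seeded sampling of conformer ensembles from a dynamic model.

# one wrapped-normal draw (degrees); sigma <= 20 deg makes the wrapped
# normal indistinguishable from a von Mises with kappa = (180/(pi*sigma))^2
rwrapnorm <- function(n, mu, sigma) wrap_angle(stats::rnorm(n, mu, sigma))

#' Sample torsion value(s) from a model element
#'
#' For a [codependent_group()] one mode is drawn from the categorical
#' occupancy distribution, then each member torsion from the wrapped normal
#' of that mode; for a single [torsion_mode()] one wrapped-normal draw.
#' Randomness comes from R's global RNG stream, so calls are reproducible
#' under `set.seed()`.
#'
#' @param mode_set a `codependent_group` or a `torsion_mode`.
#' @return for a group, list with `angles` (named vector, degrees) and
#'   `mode` (1-based index); for a single mode, list with `angles`
#'   (unnamed length-1) and `mode = 1`.
#' @export
sample_torsion <- function(mode_set) {
  if (inherits(mode_set, "torsion_mode")) {
    return(list(angles = rwrapnorm(1, mode_set$mu, mode_set$sigma), mode = 1L))
  }
  if (!inherits(mode_set, "codependent_group"))
    stop("mode_set must be a torsion_mode or codependent_group")
  k <- sample.int(length(mode_set$populations), 1L,
                  prob = mode_set$populations)
  mk <- mode_set$modes[[k]]
  ang <- vapply(mode_set$torsions,
                function(tn) rwrapnorm(1, mk[[tn]]$mu, mk[[tn]]$sigma), 0)
  list(angles = ang, mode = k)
}

# draw a full torsion set for one conformer; unimodal first, then groups,
# in model order (the documented draw order)
sample_torsion_set <- function(model) {
  angles <- numeric(0)
  modes <- integer(0)
  for (nm in names(model$unimodal))
    angles[nm] <- rwrapnorm(1, model$unimodal[[nm]]$mu,
                            model$unimodal[[nm]]$sigma)
  for (g in model$groups) {
    d <- sample_torsion(g)
    angles[names(d$angles)] <- d$angles
    modes[g$id] <- d$mode
  }
  list(angles = angles, modes = modes)
}

#' Generate a conformer ensemble
#'
#' Draws `n` torsion sets from the dynamic model (conformer-major draw
#' order: for each conformer, unimodal torsions in model order, then each
#' codependent group) and builds Cartesian coordinates with
#' [build_cartesian()]. Torsions the model does not cover but the topology
#' requires are held at `fixed_torsions`; anchor atoms (those upstream of
#' every free torsion) are bitwise identical across conformers.
#'
#' @param model a `dynamic_model`.
#' @param topology a `glyco_topology`.
#' @param n number of conformers (>= 1); 250 reproduces the ensemble size
#'   used for docking.
#' @param seed integer seed; the ensemble is a pure function of
#'   (model, topology, n, seed).
#' @param fixed_torsions named numeric vector of fixed values for torsions
#'   absent from the model.
#' @return an object of class `glyco_ensemble`: list with `conformers`
#'   (each holding `xyz`, `torsions`, `modes`), `topology`, `seed`,
#'   `model_hash`.
#' @export
generate_ensemble <- function(model, topology, n = 250, seed = 1,
                              fixed_torsions = numeric()) {
  stopifnot(n >= 1)
  need <- topology_torsions(topology)
  covered <- c(model_torsion_names(model), names(fixed_torsions))
  missing <- setdiff(need, covered)
  if (length(missing) > 0L)
    stop("model does not cover topology torsion(s): ",
         paste(missing, collapse = ", "))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  conformers <- vector("list", n)
  for (i in seq_len(n)) {
    d <- sample_torsion_set(model)
    tv <- c(d$angles, fixed_torsions[setdiff(names(fixed_torsions),
                                             names(d$angles))])
    xyz <- build_cartesian(topology, tv)
    conformers[[i]] <- list(xyz = xyz, torsions = tv, modes = d$modes)
  }
  structure(list(conformers = conformers, topology = topology,
                 seed = as.integer(seed), model_hash = model_hash(model)),
            class = "glyco_ensemble")
}

#' @export
print.glyco_ensemble <- function(x, ...) {
  cat(sprintf("Conformer ensemble: %d conformers, %d atoms, seed %d\n",
              length(x$conformers), nrow(x$conformers[[1]]$xyz), x$seed))
  ml <- ensemble_mode_labels(x)
  if (!is.null(ml)) {
    cat("mode counts:")
    print(table(ml))
  }
  invisible(x)
}

#' Mode labels of an ensemble's first codependent group
#' @param ensemble a `glyco_ensemble`.
#' @param group_id group identifier; defaults to the first group sampled.
#' @return integer vector of mode indices (one per conformer), or `NULL`
#'   when no group was sampled.
#' @export
ensemble_mode_labels <- function(ensemble, group_id = NULL) {
  m1 <- ensemble$conformers[[1]]$modes
  if (length(m1) == 0L) return(NULL)
  if (is.null(group_id)) group_id <- names(m1)[1]
  vapply(ensemble$conformers, function(cf) cf$modes[[group_id]], 0L)
}

# ---- multi-model PDB output ---------------------------------------------

pdb_atom_name <- function(id) {
  a <- sub("^\\S+ ", "", id)
  if (a == "OG") a <- "OG1"
  substr(sprintf("%-4s", a), 1, 4)
}

#' Write an ensemble as a multi-model PDB file
#'
#' Standard MODEL/ENDMDL blocks with HETATM records (one model per
#' conformer, serial numbers 1-based, residue numbers from the topology
#' labels); REMARK lines carry the generator seed and per-model mode
#' labels, so a write-read-write round trip is byte identical.
#'
#' @param ensemble a `glyco_ensemble`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ensemble_pdb <- function(ensemble, path) {
  if (!nzchar(path)) stop("empty output path")
  topo <- ensemble$topology
  res <- topo$atoms$residue
  resno <- as.integer(factor(res, levels = unique(res)))
  el <- topo$atoms$element
  lines <- c(sprintf("REMARK 250 GLYCODYN ENSEMBLE SEED %d", ensemble$seed),
             sprintf("REMARK 250 MODEL HASH %s", ensemble$model_hash))
  for (m in seq_along(ensemble$conformers)) {
    cf <- ensemble$conformers[[m]]
    lines <- c(lines,
               sprintf("REMARK 250 MODEL %d MODES %s", m,
                       if (length(cf$modes)) paste(names(cf$modes),
                                                   cf$modes, sep = "=",
                                                   collapse = " ")
                       else "none"),
               sprintf("MODEL     %4d", m))
    xyz <- cf$xyz
    for (i in seq_len(nrow(xyz))) {
      lines <- c(lines, sprintf(
        "HETATM%5d %s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
        i, pdb_atom_name(topo$atoms$id[i]), substr(res[i], 1, 3), resno[i],
        xyz[i, 1], xyz[i, 2], xyz[i, 3], el[i]))
    }
    lines <- c(lines, "ENDMDL")
  }
  lines <- c(lines, "END")
  writeLines(lines, path)
  invisible(path)
}

#' Read a multi-model PDB written by [write_ensemble_pdb()]
#'
#' Restores coordinates (at PDB precision, 0.001 A), seed and mode labels;
#' atom identifiers are reconstructed from the residue/atom name fields.
#'
#' @param path PDB file path.
#' @param topology the `glyco_topology` the file was written from.
#' @return a `glyco_ensemble` (torsion values re-measured from the
#'   coordinates for the topology's free torsions).
#' @export
read_ensemble_pdb <- function(path, topology) {
  lines <- readLines(path)
  seed <- as.integer(sub("^REMARK 250 GLYCODYN ENSEMBLE SEED ", "",
                         grep("^REMARK 250 GLYCODYN ENSEMBLE SEED",
                              lines, value = TRUE)[1]))
  hash <- sub("^REMARK 250 MODEL HASH ", "",
              grep("^REMARK 250 MODEL HASH", lines, value = TRUE)[1])
  mode_lines <- grep("^REMARK 250 MODEL [0-9]+ MODES", lines, value = TRUE)
  starts <- grep("^MODEL", lines)
  ends <- grep("^ENDMDL", lines)
  stopifnot(length(starts) == length(ends))
  tnames <- topology_torsions(topology)
  conformers <- vector("list", length(starts))
  for (m in seq_along(starts)) {
    block <- lines[(starts[m] + 1):(ends[m] - 1)]
    block <- block[grepl("^(ATOM|HETATM)", block)]
    xyz <- matrix(NA_real_, length(block), 3,
                  dimnames = list(topology$atoms$id, NULL))
    for (i in seq_along(block)) {
      xyz[i, ] <- as.numeric(c(substr(block[i], 31, 38),
                               substr(block[i], 39, 46),
                               substr(block[i], 47, 54)))
    }
    tv <- vapply(tnames, function(tn)
      measure_torsion(xyz, topology$torsion_atoms[[tn]]), 0)
    modes <- integer(0)
    ml <- mode_lines[m]
    if (!is.na(ml) && !grepl("MODES none", ml)) {
      spec <- sub("^REMARK 250 MODEL [0-9]+ MODES ", "", ml)
      kv <- strsplit(strsplit(spec, " ")[[1]], "=")
      modes <- stats::setNames(vapply(kv, function(p) as.integer(p[2]), 0L),
                               vapply(kv, `[[`, "", 1))
    }
    conformers[[m]] <- list(xyz = xyz, torsions = tv, modes = modes)
  }
  structure(list(conformers = conformers, topology = topology,
                 seed = seed, model_hash = hash),
            class = "glyco_ensemble")
}
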