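# End-to-end orchestration: structural runs (model -> ensemble -> dock ->
# report) and thermodynamic runs (titration CSVs -> fits -> summary
# tables), with a reproducibility manifest.

log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run configuration
#'
#' @param model a `dynamic_model` or path to a model JSON.
#' @param topology a `glyco_topology`, a path to a topology JSON, or a
#'   preset string (`"ha6-2aa"`, `"ha4-2aa"`).
#' @param pocket a `binding_pocket`, a pocket JSON path, or `"fixture"`
#'   for [make_pocket_fixture()].
#' @param restraints optional `restraint_set` or CSV path.
#' @param thermo_dir optional directory of titration / dose-response CSVs.
#' @param n_conformers ensemble size (default 250).
#' @param seed integer seed.
#' @param outdir output directory (created if missing).
#' @return an object of class `run_config`.
#' @export
run_config <- function(model = NULL, topology = "ha6-2aa",
                       pocket = "fixture", restraints = NULL,
                       thermo_dir = NULL, n_conformers = 250, seed = 1,
                       outdir = tempfile("glycodyn_run_")) {
  stopifnot(n_conformers >= 1)
  structure(list(model = model, topology = topology, pocket = pocket,
                 restraints = restraints, thermo_dir = thermo_dir,
                 n_conformers = as.integer(n_conformers),
                 seed = as.integer(seed), outdir = outdir),
            class = "run_config")
}

resolve_model <- function(x) {
  if (is.null(x)) return(ha4_2aa_model())
  if (inherits(x, "dynamic_model")) return(x)
  if (is.character(x)) {
    if (!file.exists(x)) stop("missing model file: ", x)
    return(load_dynamic_model(x))
  }
  stop("cannot interpret model input")
}

resolve_topology <- function(x) {
  if (inherits(x, "glyco_topology")) return(x)
  if (is.character(x)) {
    if (x == "ha6-2aa") return(ha_topology(6, "2AA"))
    if (x == "ha4-2aa") return(ha_topology(4, "2AA"))
    if (!file.exists(x)) stop("missing topology file: ", x)
    return(load_topology(x))
  }
  stop("cannot interpret topology input")
}

write_manifest <- function(outdir, config_desc, files) {
  manifest <- list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config_desc,
    files = lapply(files, function(f)
      list(name = basename(f), md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Run the structural pipeline
#'
#' Sample -> build -> dock -> group: generates the conformer ensemble from
#' the dynamic model, writes it as multi-model PDB, docks it into the
#' pocket, writes per-pose scores and the per-mode summary, optionally
#' validates restraints, and writes a manifest with content hashes of
#' every output. Reruns with an identical configuration produce identical
#' score/summary files.
#'
#' @param config a [run_config()].
#' @return the output directory, invisibly; errors abort with the stage
#'   name.
#' @export
run_structural <- function(config) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    log_stage(name, "started")
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  model <- stage("model", resolve_model(config$model))
  topology <- stage("topology", resolve_topology(config$topology))
  pocket <- stage("pocket", {
    p <- config$pocket
    if (inherits(p, "binding_pocket")) p
    else if (identical(p, "fixture"))
      make_pocket_fixture(topology = topology, model = model)$pocket
    else {
      if (!file.exists(p)) stop("missing pocket file: ", p)
      x <- jsonlite::read_json(p, simplifyVector = TRUE)
      ar <- do.call(rbind, x$anchor_reference$xyz)
      rownames(ar) <- x$anchor_reference$atom
      binding_pocket(as.data.frame(x$sites), ar)
    }
  })
  ensemble <- stage("ensemble",
                    generate_ensemble(model, topology,
                                      n = config$n_conformers,
                                      seed = config$seed))
  files <- character(0)
  f_ens <- file.path(config$outdir, "ensemble.pdb")
  stage("write-ensemble", write_ensemble_pdb(ensemble, f_ens))
  files <- c(files, f_ens)

  docking <- stage("dock", rank_ensemble(ensemble, pocket, model))
  f_scores <- file.path(config$outdir, "scores.csv")
  write_scores_csv(docking, f_scores)
  f_summary <- file.path(config$outdir, "mode_summary.csv")
  utils::write.csv(docking$summary, f_summary, row.names = FALSE)
  files <- c(files, f_scores, f_summary)

  if (!is.null(config$restraints)) {
    set <- stage("restraints", {
      r <- config$restraints
      if (inherits(r, "restraint_set")) r else read_restraints(r)
    })
    rep <- check_restraints(ensemble, set)
    f_rep <- file.path(config$outdir, "restraint_report.csv")
    utils::write.csv(as.data.frame(rep), f_rep, row.names = FALSE)
    files <- c(files, f_rep)
  }

  stage("manifest", write_manifest(
    config$outdir,
    list(kind = "structural", n_conformers = config$n_conformers,
         seed = config$seed, model_hash = model_hash(model),
         topology = sprintf("%d residues (%s)", topology$n_residues,
                            topology$modification)),
    files))
  log_stage("done", config$outdir)
  invisible(config$outdir)
}

#' Write a simulated titration to CSV
#'
#' Columns `injection_index, volume_ul, heat, unit` plus the cell
#' bookkeeping columns the reader needs.
#'
#' @param data a `titration_data`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_itc_csv <- function(data, path) {
  utils::write.csv(data.frame(
    injection_index = seq_along(data$heats),
    volume_ul = data$injection_volumes * 1e6,
    heat = data$heats, unit = "kcal",
    cell_conc_mM = data$cell_conc * 1e3,
    syringe_conc_mM = data$syringe_conc * 1e3,
    cell_volume_ul = data$cell_volume * 1e6,
    temperature_K = data$temperature), path, row.names = FALSE)
  invisible(path)
}

#' Read a titration CSV written by [write_itc_csv()]
#' @param path CSV path. A `unit` column (`kcal` or `ucal`) is mandatory.
#' @return a `titration_data`.
#' @export
read_itc_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"unit" %in% names(df)) stop("titration CSV needs a 'unit' column")
  scale <- switch(df$unit[1], kcal = 1, ucal = 1e-9,
                  stop("unknown heat unit: ", df$unit[1]))
  titration_data(df$heat * scale,
                 cell_conc = df$cell_conc_mM[1] * 1e-3,
                 syringe_conc = df$syringe_conc_mM[1] * 1e-3,
                 cell_volume = df$cell_volume_ul[1] * 1e-6,
                 injection_volumes = df$volume_ul * 1e-6,
                 temperature = df$temperature_K[1])
}

#' Write / read a dose-response CSV (`conc_M, dFnorm` + receptor column)
#' @param data a `dose_response`.
#' @param path file path.
#' @return `path` invisibly / a `dose_response`.
#' @export
write_mst_csv <- function(data, path) {
  utils::write.csv(data.frame(
    conc_M = data$ligand_concs, dFnorm = data$responses,
    receptor_M = data$receptor_conc, temperature_K = data$temperature),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mst_csv
#' @export
read_mst_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  dose_response(df$conc_M, df$dFnorm, receptor_conc = df$receptor_M[1],
                temperature = df$temperature_K[1])
}

#' Run the thermodynamics pipeline
#'
#' Fits every titration (`*_itc.csv`) and dose-response (`*_mst.csv`) file
#' in `config$thermo_dir`, writes one JSON result per experiment and a
#' replicate summary (mean and SEM over replicates grouped by the label
#' before a trailing `_repN`). Per-file fit failures are recorded and the
#' run continues; the error is re-raised at the end if any file failed.
#'
#' @param config a [run_config()] with `thermo_dir` set.
#' @return the output directory, invisibly.
#' @export
run_thermo <- function(config) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(config$thermo_dir) || !dir.exists(config$thermo_dir))
    stop("thermo_dir missing or not a directory")
  files <- list.files(config$thermo_dir, pattern = "_(itc|mst)\\.csv$",
                      full.names = TRUE)
  if (length(files) == 0L) stop("no *_itc.csv / *_mst.csv inputs in ",
                                config$thermo_dir)
  rows <- list(); outputs <- character(0); failures <- character(0)
  for (f in sort(files)) {
    label <- sub("_(itc|mst)\\.csv$", "", basename(f))
    kind <- if (grepl("_itc\\.csv$", f)) "ITC" else "MST"
    log_stage("fit", label, " (", kind, ")")
    res <- tryCatch({
      if (kind == "ITC") fit_itc(read_itc_csv(f))
      else fit_mst(read_mst_csv(f))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("%s: %s", basename(f),
                                      conditionMessage(res)))
      next
    }
    fj <- file.path(config$outdir, paste0(label, "_result.json"))
    jsonlite::write_json(
      list(label = label, method = kind, K_D = res$K_D,
           delta_G = res$delta_G, delta_H = res$delta_H, N = res$N,
           minus_T_delta_S = res$minus_T_delta_S,
           se = as.list(res$se)),
      fj, auto_unbox = TRUE, digits = NA)
    outputs <- c(outputs, fj)
    rows[[length(rows) + 1L]] <- data.frame(
      label = label, group = sub("_rep[0-9]+$", "", label), method = kind,
      kd = res$K_D, dG = res$delta_G, dH = res$delta_H, n = res$N,
      mTdS = res$minus_T_delta_S, stringsAsFactors = FALSE)
  }
  if (length(rows) > 0L) {
    df <- do.call(rbind, rows)
    sem <- function(x) if (sum(is.finite(x)) > 1)
      stats::sd(x[is.finite(x)]) / sqrt(sum(is.finite(x))) else NA_real_
    agg <- do.call(rbind, lapply(split(df, df$group), function(d)
      data.frame(group = d$group[1], method = d$method[1],
                 n_replicates = nrow(d),
                 kd_mean = mean(d$kd), kd_sem = sem(d$kd),
                 dG_mean = mean(d$dG), dG_sem = sem(d$dG),
                 dH_mean = mean(d$dH), dH_sem = sem(d$dH),
                 N_mean = mean(d$n), N_sem = sem(d$n),
                 mTdS_mean = mean(d$mTdS), mTdS_sem = sem(d$mTdS))))
    f_sum <- file.path(config$outdir, "summary.csv")
    utils::write.csv(agg, f_sum, row.names = FALSE)
    outputs <- c(outputs, f_sum)
  }
  write_manifest(config$outdir,
                 list(kind = "thermo", inputs = basename(files),
                      failures = failures),
                 outputs)
  if (length(failures) > 0L)
    stop("thermo run completed with failures:\n  ",
         paste(failures, collapse = "\n  "))
  log_stage("done", config$outdir)
  invisible(config$outdir)
}
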