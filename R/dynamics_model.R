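#' @keywords internal
"_PACKAGE"

# ---- angle helpers -------------------------------------------------------

#' Wrap angles into (-180, 180]
#'
#' Dihedral angles throughout the package are in degrees with the IUPAC sign
#' convention, wrapped to the half-open interval (-180, 180].
#'
#' @param x numeric vector of angles in degrees.
#' @return numeric vector of the same length, wrapped to (-180, 180].
#' @export
#' @examples
#' wrap_angle(c(360, -180, 270))
wrap_angle <- function(x) {
  y <- (x + 180) %% 360 - 180
  # %% maps -180 -> -180; convention is (-180, 180]
  y[y == -180] <- 180
  y
}

# ---- constructors --------------------------------------------------------

#' Single libration mode of one torsion
#'
#' A mode is a wrapped-normal distribution of a dihedral angle: a mean
#' `mu` (degrees) and a libration width `sigma` (degrees, > 0).
#'
#' @param mu mean dihedral angle in degrees; wrapped into (-180, 180].
#' @param sigma libration width about the mean, degrees, strictly positive.
#' @return an object of class `torsion_mode`.
#' @export
torsion_mode <- function(mu, sigma) {
  stopifnot(is.numeric(mu), length(mu) == 1L, is.finite(mu))
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stop("sigma must be a single positive number")
  structure(list(mu = wrap_angle(mu), sigma = as.numeric(sigma)),
            class = "torsion_mode")
}

#' Declare a named torsion
#'
#' @param name unique text label, e.g. `"T4 C2-C3"`.
#' @param atoms character vector of four distinct atom identifiers defining
#'   the dihedral.
#' @param group identifier of the codependent group this torsion belongs to,
#'   or `NA` for unimodal torsions.
#' @return an object of class `torsion_spec`.
#' @export
torsion_spec <- function(name, atoms, group = NA_character_) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (length(atoms) != 4L || anyDuplicated(atoms))
    stop("atoms must be four distinct identifiers")
  structure(list(name = name, atoms = as.character(atoms),
                 group = as.character(group)),
            class = "torsion_spec")
}

#' Codependent group of torsions with joint modes
#'
#' Several torsions that switch conformation together. Each mode assigns one
#' [torsion_mode()] per member torsion; `populations` are the mode
#' occupancies (fractions summing to 1).
#'
#' @param id group identifier.
#' @param torsions character vector of member torsion names (ordered).
#' @param modes list of modes; each mode is a named list of [torsion_mode()]
#'   objects, one per torsion in `torsions`.
#' @param populations numeric vector of mode occupancies, one per mode.
#' @param pop_tol renormalise silently when `sum(populations)` is within
#'   this tolerance of 1, otherwise error. Default `1e-6`.
#' @return an object of class `codependent_group`.
#' @export
codependent_group <- function(id, torsions, modes, populations,
                              pop_tol = 1e-6) {
  stopifnot(length(torsions) >= 1L, length(modes) >= 1L)
  if (length(populations) != length(modes))
    stop("need one population per mode")
  if (any(populations < 0)) stop("populations must be non-negative")
  s <- sum(populations)
  if (abs(s - 1) > pop_tol)
    stop(sprintf("populations sum to %.9g, not 1 (tolerance %g)", s, pop_tol))
  populations <- populations / s
  modes <- lapply(modes, function(m) {
    if (!all(torsions %in% names(m)))
      stop("each mode must assign a torsion_mode to every member torsion")
    m[torsions]
  })
  structure(list(id = as.character(id), torsions = as.character(torsions),
                 modes = modes, populations = as.numeric(populations)),
            class = "codependent_group")
}

#' Dynamic torsion model
#'
#' The complete description of the solution dynamics of a flexible molecular
#' fragment: unimodal torsions (one wrapped-normal mode each) plus
#' codependent groups of multimodal torsions.
#'
#' @param unimodal named list of [torsion_mode()] objects, keyed by torsion
#'   name.
#' @param groups list of [codependent_group()] objects.
#' @param torsions optional list of [torsion_spec()] records declaring the
#'   atom quadruples; purely descriptive for model handling, required when
#'   the model is used against a topology.
#' @param metadata free-text provenance string.
#' @return an object of class `dynamic_model`.
#' @export
dynamic_model <- function(unimodal = list(), groups = list(),
                          torsions = list(), metadata = "") {
  m <- structure(list(unimodal = unimodal, groups = groups,
                      torsions = torsions, metadata = metadata),
                 class = "dynamic_model")
  rep <- validate_model(m)
  if (nrow(rep) > 0L)
    stop("invalid dynamic model:\n  ",
         paste(rep$message, collapse = "\n  "))
  m
}

#' All torsion names covered by a model
#' @param model a `dynamic_model`.
#' @return character vector of torsion names (unimodal then grouped).
#' @export
model_torsion_names <- function(model) {
  c(names(model$unimodal),
    unlist(lapply(model$groups, `[[`, "torsions"), use.names = FALSE))
}

#' Mode populations of a codependent group
#'
#' @param model a `dynamic_model`.
#' @param group_id identifier of the group.
#' @return numeric vector of occupancies in mode order (sums to 1).
#' @export
mode_populations <- function(model, group_id) {
  ids <- vapply(model$groups, `[[`, "", "id")
  i <- match(group_id, ids)
  if (is.na(i)) stop("unknown group id: ", group_id)
  model$groups[[i]]$populations
}

# ---- validation ----------------------------------------------------------

#' Validate a dynamic model
#'
#' Checks every structural invariant and returns a report instead of
#' erroring: positive libration widths, population sums within `1e-9` after
#' construction-time renormalisation, complete per-mode assignments, unique
#' torsion names, and no torsion listed both as unimodal and in a group.
#'
#' @param model a `dynamic_model` (or a bare list with the same fields).
#' @return a data.frame with columns `where` and `message`; zero rows iff
#'   the model is valid.
#' @export
validate_model <- function(model) {
  bad <- list()
  note <- function(where, message)
    bad[[length(bad) + 1L]] <<- data.frame(where = where, message = message)

  for (nm in names(model$unimodal)) {
    md <- model$unimodal[[nm]]
    if (!is.finite(md$sigma) || md$sigma <= 0)
      note(nm, sprintf("unimodal torsion '%s': sigma must be > 0", nm))
  }
  for (g in model$groups) {
    if (length(g$modes) < 1L)
      note(g$id, sprintf("group '%s': needs at least one mode", g$id))
    s <- sum(g$populations)
    if (abs(s - 1) > 1e-9)
      note(g$id, sprintf("group '%s': populations sum to %.12g", g$id, s))
    if (any(g$populations < 0))
      note(g$id, sprintf("group '%s': negative population", g$id))
    for (k in seq_along(g$modes)) {
      mk <- g$modes[[k]]
      if (!all(g$torsions %in% names(mk))) {
        note(g$id, sprintf("group '%s' mode %d: missing torsion assignment",
                           g$id, k))
        next
      }
      for (tn in g$torsions) {
        md <- mk[[tn]]
        if (!is.finite(md$sigma) || md$sigma <= 0)
          note(g$id, sprintf("group '%s' mode %d torsion '%s': sigma must be > 0",
                             g$id, k, tn))
      }
    }
  }
  nms <- model_torsion_names(model)
  if (anyDuplicated(nms))
    note("model", paste("duplicate torsion name(s):",
                        paste(unique(nms[duplicated(nms)]), collapse = ", ")))
  if (length(bad) == 0L)
    return(data.frame(where = character(), message = character()))
  do.call(rbind, bad)
}

# ---- serialisation -------------------------------------------------------

model_to_list <- function(model) {
  list(
    metadata = model$metadata,
    torsions = lapply(model$torsions, function(t)
      list(name = t$name, atoms = t$atoms, group = t$group)),
    unimodal = lapply(model$unimodal, function(m)
      list(mu = m$mu, sigma = m$sigma)),
    groups = lapply(model$groups, function(g) list(
      id = g$id, torsions = g$torsions,
      modes = mapply(function(mode, pop) list(
        assignments = lapply(mode, function(m) list(mu = m$mu, sigma = m$sigma)),
        population = pop),
        g$modes, g$populations, SIMPLIFY = FALSE)))
  )
}

model_from_list <- function(x, pop_tol = 1e-6) {
  unimodal <- lapply(x$unimodal, function(m) torsion_mode(m$mu, m$sigma))
  groups <- lapply(x$groups, function(g) {
    modes <- lapply(g$modes, function(mo)
      lapply(mo$assignments, function(a) torsion_mode(a$mu, a$sigma)))
    pops <- vapply(g$modes, function(mo) as.numeric(mo$population), 0)
    codependent_group(g$id, unlist(g$torsions), modes, pops, pop_tol = pop_tol)
  })
  torsions <- lapply(x$torsions, function(t)
    torsion_spec(t$name, unlist(t$atoms),
                 if (is.null(t$group) || length(t$group) == 0) NA_character_
                 else t$group))
  dynamic_model(unimodal = unimodal, groups = groups, torsions = torsions,
                metadata = if (is.null(x$metadata)) "" else x$metadata)
}

#' Read a dynamic model from file
#'
#' JSON is the canonical format (codependent groups are nested); CSV is
#' accepted for flat unimodal-only models with columns
#' `name, mu, sigma` and optionally `a1, a2, a3, a4`.
#'
#' @param path file path.
#' @param format `"json"` or `"csv"`; guessed from the extension by default.
#' @param pop_tol tolerance on group population sums; sums within `pop_tol`
#'   of 1 are renormalised silently, anything further is an error.
#' @return a validated `dynamic_model`.
#' @export
load_dynamic_model <- function(path, format = c("auto", "json", "csv"),
                               pop_tol = 1e-6) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "json") {
    x <- jsonlite::read_json(path, simplifyVector = FALSE)
    return(model_from_list(x, pop_tol = pop_tol))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "mu", "sigma")
  if (!all(need %in% names(df)))
    stop("CSV model needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$name))
    stop("duplicate torsion name in CSV model")
  unimodal <- stats::setNames(
    lapply(seq_len(nrow(df)), function(i) torsion_mode(df$mu[i], df$sigma[i])),
    df$name)
  torsions <- if (all(c("a1", "a2", "a3", "a4") %in% names(df))) {
    lapply(seq_len(nrow(df)), function(i)
      torsion_spec(df$name[i], c(df$a1[i], df$a2[i], df$a3[i], df$a4[i])))
  } else list()
  dynamic_model(unimodal = unimodal, torsions = torsions,
                metadata = paste("loaded from", basename(path)))
}

#' Write a dynamic model to JSON
#'
#' Round-trips: `load_dynamic_model(write_dynamic_model(m, f))` restores `m`
#' field-wise (with angle wrapping applied).
#'
#' @param model a `dynamic_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dynamic_model <- function(model, path) {
  jsonlite::write_json(model_to_list(model), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Stable digest of a dynamic model
#'
#' Used to stamp ensembles with the model that generated them.
#'
#' @param model a `dynamic_model`.
#' @return an md5 string.
#' @export
model_hash <- function(model) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(model_to_list(model), auto_unbox = TRUE,
                              digits = 12), f)
  unname(tools::md5sum(f))
}

#' @export
print.dynamic_model <- function(x, ...) {
  cat("Dynamic torsion model:",
      length(x$unimodal), "unimodal torsion(s),",
      length(x$groups), "codependent group(s)\n")
  for (g in x$groups)
    cat(sprintf("  group '%s': %d torsions x %d modes; pi = %s\n",
                g$id, length(g$torsions), length(g$modes),
                paste(format(g$populations), collapse = ", ")))
  invisible(x)
}
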