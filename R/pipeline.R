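# End-to-end orchestration: alignment check, per-channel rasterisation,
# model fitting with the full validation battery, report export, and the
# optional design and docking-evaluation stages.

#' Pipeline run configuration
#'
#' Collects every tunable of a full run. Either `generator` (a
#' [generator_config()], for synthetic data) or `sketch_path` +
#' `activity_path` must be given. The single `seed` drives every random
#' stage (permutations, bootstrap holdouts) through fixed offsets, so a
#' rerun with the same config is bit-identical.
#'
#' @param output_dir Directory for reports (created if absent).
#' @param generator Optional [generator_config()].
#' @param sketch_path,sketch_dialect,activity_path Input files when not
#'   simulating.
#' @param property_path Optional CSV overriding the bundled element table.
#' @param spec Canvas specification.
#' @param channels Property channels to model.
#' @param A_max Largest PLS component count scanned.
#' @param frac,n_iter Bootstrap external-validation settings.
#' @param n_perm Y-randomization permutations.
#' @param resid_threshold,leverage_factor Williams-plot cutoffs.
#' @param alignment_tol Core-alignment tolerance (template units).
#' @param core_atoms Integer indices of the shared core (defaults to the
#'   bundled scaffold when simulating).
#' @param candidate_sets Optional named list for the design stage.
#' @param reference_pki Reference activity for candidate ranking.
#' @param pose_csv,energy_csv Optional docking-evaluation inputs
#'   (`pose_id, rmsd` / decomposition columns).
#' @param da_limits RMSD limits `c(l, h)` for the Docking Accuracy score.
#' @param seed Master seed.
#' @return List of class `mia_run_config`.
#' @export
run_config <- function(output_dir, generator = NULL, sketch_path = NULL,
                       sketch_dialect = "sdf", activity_path = NULL,
                       property_path = NULL, spec = canvas_spec(),
                       channels = c("r_vdw", "epsilon", "ratio"),
                       A_max = 10L, frac = 0.25, n_iter = 10L, n_perm = 50L,
                       resid_threshold = 2.5, leverage_factor = 3,
                       alignment_tol = 1e-3, core_atoms = NULL,
                       candidate_sets = NULL, reference_pki = 7.699,
                       pose_csv = NULL, energy_csv = NULL, da_limits = c(2, 3),
                       seed = 1L) {
  if (is.null(generator) && (is.null(sketch_path) || is.null(activity_path)))
    stop("either a generator config or sketch_path + activity_path is required")
  if (!is.null(sketch_path) && !file.exists(sketch_path))
    stop("no such sketch file: ", sketch_path)
  if (!is.null(activity_path) && !file.exists(activity_path))
    stop("no such activity file: ", activity_path)
  stopifnot(length(da_limits) == 2, da_limits[1] < da_limits[2])
  channels <- match.arg(channels, c("r_vdw", "epsilon", "ratio"),
                        several.ok = TRUE)
  structure(as.list(environment()), class = "mia_run_config")
}

#' Run the full MIA-QSAR pipeline
#'
#' Stages, in order: data acquisition (simulate or read), core-alignment
#' check, per-channel rasterisation, per-channel model fitting and
#' validation battery, cross-channel report, then the optional design and
#' docking-evaluation stages. Reports are written to
#' `config$output_dir`: `validation_report.csv` (channel x statistic
#' table), `williams_<channel>.csv`, `candidates.csv` (if designed),
#' `docking_eval.json` (if requested) and `run_manifest.json` recording
#' the configuration and seeds.
#'
#' @param config From [run_config()].
#' @return List of class `mia_run` with the fitted per-channel validations,
#'   report, candidate ranking and docking evaluation (where run).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "mia_run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  props <- load_property_table(config$property_path)

  if (!is.null(config$generator)) {
    ds <- generate_dataset(config$generator)
    sketches <- ds$sketches
    acts <- as_activities(ds$activities)
    core <- config$core_atoms %||% core_atom_indices()
  } else {
    sketches <- read_sketches(config$sketch_path, config$sketch_dialect)
    acts <- load_activities(config$activity_path)
    core <- config$core_atoms
    ds <- NULL
  }
  joined <- match_activities(sketches, acts)
  sketches <- joined$sketches
  y <- joined$y

  if (!is.null(core)) {
    al <- check_alignment(sketches, core, tol = config$alignment_tol)
    if (!al$pass)
      stop("alignment check failed; worst sketch '",
           names(which.max(al$max_deviation)), "' deviates ",
           signif(max(al$max_deviation), 3), " template units")
  } else al <- NULL

  validations <- list()
  for (ch in config$channels) {
    desc <- build_descriptor_matrix(sketches, ch, config$spec, props)
    validations[[ch]] <- tryCatch(
      validate_channel(desc, y, A_max = config$A_max, frac = config$frac,
                       n_iter = config$n_iter, n_perm = config$n_perm,
                       seed = config$seed + 10L * match(ch, config$channels)),
      error = function(e) stop("validation stage failed for channel ", ch,
                               ": ", conditionMessage(e)))
    wil <- validations[[ch]]$williams
    wil$id <- vapply(sketches, `[[`, character(1), "id")
    write.csv(as.data.frame(wil),
              file.path(config$output_dir, paste0("williams_", ch, ".csv")),
              row.names = FALSE)
  }
  report <- channel_summary(lapply(validations, `[[`, "stats"))
  write_validation_csv(report, file.path(config$output_dir, "validation_report.csv"))

  ranking <- NULL
  if (!is.null(config$candidate_sets)) {
    cands <- enumerate_candidates(config$candidate_sets)
    models <- lapply(validations, `[[`, "model")
    recs <- predict_candidates(cands, models, props)
    ranking <- rank_vs_reference(recs, config$reference_pki)
    write.csv(as.data.frame(ranking),
              file.path(config$output_dir, "candidates.csv"), row.names = FALSE)
  }

  dock <- NULL
  if (!is.null(config$pose_csv) || !is.null(config$energy_csv)) {
    dock <- list()
    if (!is.null(config$pose_csv)) {
      pr <- read.csv(config$pose_csv)
      dock$docking_accuracy <- docking_accuracy(pr$rmsd, config$da_limits[1],
                                                config$da_limits[2])
    }
    if (!is.null(config$energy_csv))
      dock$energy_totals <- total_binding_energy(read.csv(config$energy_csv))
    jsonlite::write_json(dock, file.path(config$output_dir, "docking_eval.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }

  manifest <- list(
    seed = config$seed,
    channels = config$channels,
    n_samples = length(y),
    canvas = config$spec[c("width", "height", "background", "scale", "origin")],
    A_max = config$A_max, frac = config$frac, n_iter = config$n_iter,
    n_perm = config$n_perm, alignment_tol = config$alignment_tol,
    generator_seed = if (!is.null(config$generator)) config$generator$seed,
    timestamp_free = TRUE)
  jsonlite::write_json(manifest, file.path(config$output_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  structure(list(validations = validations, report = report,
                 alignment = al, ranking = ranking, docking = dock,
                 data = ds, y = y, config = config),
            class = "mia_run")
}

#' @export
print.mia_run <- function(x, ...) {
  cat("MIA-QSAR pipeline run (", length(x$y), " samples, channels: ",
      paste(x$config$channels, collapse = ", "), ")\n", sep = "")
  print(x$report)
  if (!is.null(x$ranking))
    cat("\nCandidates above reference (pKi ",
        attr(x$ranking, "reference_pki"), "): ",
        attr(x$ranking, "n_above"), " of ", nrow(x$ranking), "\n", sep = "")
  invisible(x)
}

# -- model serialization -----------------------------------------------------

#' Save / load a fitted PLS model as JSON
#'
#' The bundle records every matrix of the model plus the descriptor
#' metadata (canvas, channel, kept columns) needed to predict new sketches.
#' Arrays are stored at full double precision.
#'
#' @param model Fitted `mia_pls`.
#' @param path JSON file path.
#' @return `path` (`save_model`) or the restored model (`load_model`).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "mia_pls"))
  payload <- list(
    n_components = model$n_components, x_mean = model$x_mean,
    y_mean = model$y_mean, x_scale = model$x_scale,
    weights = model$weights, loadings = model$loadings,
    y_loadings = model$y_loadings, scores = model$scores,
    coefficients = model$coefficients, intercept = model$intercept,
    ss_y = model$ss_y, fitted = model$fitted.values, y = model$y,
    scaled = model$scaled,
    meta = if (!is.null(model$meta)) list(
      kept_columns = model$meta$kept_columns,
      channel = model$meta$channel,
      n_pixels = model$meta$n_pixels,
      spec = unclass(model$meta$spec)))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  meta <- if (!is.null(p$meta)) {
    sp <- p$meta$spec
    list(kept_columns = as.integer(p$meta$kept_columns),
         channel = p$meta$channel, n_pixels = as.integer(p$meta$n_pixels),
         spec = canvas_spec(sp$width, sp$height, sp$background, sp$scale,
                            unlist(sp$origin), sp$bond_intensity))
  }
  structure(list(n_components = as.integer(p$n_components),
                 x_mean = p$x_mean, y_mean = p$y_mean, x_scale = p$x_scale,
                 weights = as.matrix(p$weights), loadings = as.matrix(p$loadings),
                 y_loadings = p$y_loadings, scores = as.matrix(p$scores),
                 coefficients = p$coefficients, intercept = p$intercept,
                 ss_y = p$ss_y, fitted.values = p$fitted,
                 residuals = p$y - p$fitted, y = p$y, scaled = p$scaled,
                 meta = meta),
            class = "mia_pls")
}
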