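# Pipeline and file interchange: table schemas and validation, YAML run
# configuration, and the end-to-end run (simulate -> power fits -> d' with
# bootstrap -> model fits -> comparison) with a reproducibility manifest.

#' Validate a trial-level response table
#'
#' Checks the `responses` schema: required columns, positive distances,
#' responses in \{0, 1\}, and uniqueness of (subject, visual, auditory,
#' trial).
#'
#' @param responses data.frame to check.
#' @return the table, invisibly, if valid; otherwise an error.
#' @export
validate_responses <- function(responses) {
  need <- c("subject_id", "visual_m", "auditory_m", "trial_idx", "response")
  miss <- setdiff(need, names(responses))
  if (length(miss)) stop("responses table missing columns: ",
                         paste(miss, collapse = ", "))
  if (nrow(responses) == 0) stop("responses table is empty")
  if (any(responses$visual_m <= 0) || any(responses$auditory_m <= 0))
    stop("responses table has nonpositive distances")
  if (!all(responses$response %in% c(0, 1)))
    stop("response values must be 0 or 1")
  key <- paste(responses$subject_id, responses$visual_m,
               responses$auditory_m, responses$trial_idx)
  if (anyDuplicated(key))
    stop("duplicate (subject, visual, auditory, trial) rows")
  invisible(responses)
}

#' Validate an absolute-judgment table
#'
#' Checks the `absolute` schema: required columns, modalities in
#' \{"aud", "vis"\}, positive distances and judgments.
#'
#' @param judgments data.frame to check.
#' @return the table, invisibly, if valid; otherwise an error.
#' @export
validate_judgments <- function(judgments) {
  need <- c("subject_id", "modality", "target_m", "judged_m")
  miss <- setdiff(need, names(judgments))
  if (length(miss)) stop("judgment table missing columns: ",
                         paste(miss, collapse = ", "))
  if (nrow(judgments) == 0) stop("judgment table is empty")
  if (!all(judgments$modality %in% c("aud", "vis")))
    stop("modality must be 'aud' or 'vis'")
  if (any(judgments$target_m <= 0) || any(judgments$judged_m <= 0))
    stop("judgment table has nonpositive distances")
  invisible(judgments)
}

#' Validate CSV tables on disk
#'
#' Reads each file and checks it against the schema implied by its name
#' (`responses*.csv`, `absolute*.csv`, or `cues*.csv`): column presence,
#' value ranges, and key uniqueness. Problems are collected, not raised, so
#' one bad file does not mask diagnostics for the others.
#'
#' @param paths character vector of CSV paths.
#' @return data.frame with one row per file: `file`, `schema`, `pass`,
#'   `n_issues`; attribute `issues` holds a row-level data.frame
#'   (`file`, `row`, `reason`).
#' @export
validate_tables <- function(paths) {
  issues <- list()
  note <- function(file, row, reason)
    issues[[length(issues) + 1]] <<- data.frame(file = file, row = row,
                                                reason = reason)
  report <- lapply(paths, function(p) {
    schema <- if (grepl("response", basename(p))) "responses"
      else if (grepl("absolute", basename(p))) "absolute"
      else if (grepl("cue", basename(p))) "cues"
      else "unknown"
    tab <- tryCatch(suppressWarnings(utils::read.csv(p)),
                    error = function(e) e)
    if (inherits(tab, "error")) {
      note(p, NA_integer_, paste("unreadable:", conditionMessage(tab)))
      return(data.frame(file = p, schema = schema, pass = FALSE))
    }
    if (schema == "responses") {
      for (col in c("subject_id", "visual_m", "auditory_m", "trial_idx",
                    "response"))
        if (!col %in% names(tab)) note(p, NA_integer_,
                                       paste("missing column", col))
      if (all(c("visual_m", "auditory_m") %in% names(tab))) {
        bad <- which(tab$visual_m <= 0 | tab$auditory_m <= 0)
        for (i in bad) note(p, i, "nonpositive distance")
      }
      if ("response" %in% names(tab)) {
        bad <- which(!tab$response %in% c(0, 1))
        for (i in bad) note(p, i, "response not in {0, 1}")
      }
      if (all(c("subject_id", "visual_m", "auditory_m", "trial_idx")
              %in% names(tab))) {
        key <- paste(tab$subject_id, tab$visual_m, tab$auditory_m,
                     tab$trial_idx)
        for (i in which(duplicated(key))) note(p, i, "duplicate trial key")
      }
    } else if (schema == "absolute") {
      for (col in c("subject_id", "modality", "target_m", "judged_m"))
        if (!col %in% names(tab)) note(p, NA_integer_,
                                       paste("missing column", col))
      if ("modality" %in% names(tab))
        for (i in which(!tab$modality %in% c("aud", "vis")))
          note(p, i, "unknown modality")
      if (all(c("target_m", "judged_m") %in% names(tab))) {
        bad <- which(tab$target_m <= 0 | tab$judged_m <= 0)
        for (i in bad) note(p, i, "nonpositive distance or judgment")
      }
    } else if (schema == "cues") {
      for (col in c("distance_m", "level_db", "drr_db"))
        if (!col %in% names(tab)) note(p, NA_integer_,
                                       paste("missing column", col))
      if ("distance_m" %in% names(tab)) {
        for (i in which(tab$distance_m <= 0)) note(p, i, "nonpositive distance")
        if (anyDuplicated(tab$distance_m))
          note(p, NA_integer_, "duplicate distances")
        if (is.unsorted(tab$distance_m))
          note(p, NA_integer_, "distances not ascending")
      }
    } else {
      note(p, NA_integer_, "unrecognized table name")
    }
    n_bad <- sum(vapply(issues, function(d) d$file[1] == p, logical(1)))
    data.frame(file = p, schema = schema, pass = n_bad == 0)
  })
  out <- do.call(rbind, report)
  iss <- if (length(issues)) do.call(rbind, issues) else
    data.frame(file = character(), row = integer(), reason = character())
  out$n_issues <- vapply(out$file, function(f) sum(iss$file == f), numeric(1))
  rownames(out) <- NULL
  attr(out, "issues") <- iss
  out
}

#' Assemble a pipeline run configuration
#'
#' Bundles everything one end-to-end run needs: the experiment design, the
#' generating observer, model defaults, and fitting options. Every field is
#' validated by the owning constructor before any stage runs.
#'
#' @param design an `av_design` (default [default_design()]).
#' @param observer an `av_observer` (default [observer_params()]).
#' @param variants model variants to fit.
#' @param n_params free parameters per fit (1, 2, or 3).
#' @param bootstrap_B bootstrap resamples for the d' confidence intervals
#'   (0 disables the bootstrap stage).
#' @param aud_factor,vis_factor,reference_distance_m,printed_formula model
#'   defaults passed to [model_spec()].
#' @param seed root seed for simulation and bootstrap.
#' @return list of class `av_config`.
#' @export
run_config <- function(design = default_design(),
                       observer = observer_params(),
                       variants = c("M1", "M2", "M3"),
                       n_params = 2,
                       bootstrap_B = 1000,
                       aud_factor = 10^0.23, vis_factor = 10^0.15,
                       reference_distance_m = 3,
                       printed_formula = FALSE,
                       seed = 1L) {
  check_design(design)
  check_observer(observer)
  if (!all(variants %in% c("M1", "M2", "M3"))) stop("unknown model variant")
  if (!n_params %in% 1:3) stop("n_params must be 1, 2, or 3")
  if (bootstrap_B < 0) stop("bootstrap_B must be >= 0")
  structure(list(design = design, observer = observer, variants = variants,
                 n_params = n_params, bootstrap_B = bootstrap_B,
                 aud_factor = aud_factor, vis_factor = vis_factor,
                 reference_distance_m = reference_distance_m,
                 printed_formula = printed_formula,
                 seed = as.integer(seed)), class = "av_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Accepts a flat YAML tree with optional sections `design`, `observer`,
#' and `fitting`; keys within each section are passed to
#' [experiment_design()], [observer_params()], and [run_config()]
#' respectively. Missing keys keep their defaults. A top-level `seed`
#' overrides the observer's seed and the bootstrap seed.
#'
#' @param path YAML file path.
#' @param seed optional seed overriding the file's.
#' @return an `av_config`.
#' @export
read_run_config <- function(path, seed = NULL) {
  raw <- yaml::read_yaml(path)
  design <- do.call(experiment_design, raw$design %||% list())
  obs_args <- raw$observer %||% list()
  fit_args <- raw$fitting %||% list()
  if (!is.null(seed)) raw$seed <- seed
  if (!is.null(raw$seed)) obs_args$seed <- raw$seed
  observer <- do.call(observer_params, obs_args)
  do.call(run_config, c(list(design = design, observer = observer,
                             seed = observer$seed), fit_args))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_table <- function(tab, dir, name) {
  path <- file.path(dir, name)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes, in order: simulate responses and absolute judgments; fit power
#' functions to the judgments (group geometric-mean fits, plus per-subject
#' fits when `n_params` fitting is per-subject capable); compute pooled d'
#' curves with bootstrap confidence intervals; fit every requested model
#' variant per visual-target block; tabulate the RMS comparison. All stage
#' outputs are written as headered CSV files to `out_dir`, together with a
#' `manifest.txt` recording the package version, seed, effective
#' configuration hash, and per-file MD5 checksums, so a rerun with the same
#' configuration and seed is byte-identical and verifiable.
#'
#' Stage failures abort with the failing stage named; outputs of completed
#' stages are kept and a `FAILED` marker file records the stage and error.
#'
#' @param config an `av_config` from [run_config()] or [read_run_config()].
#' @param out_dir output directory (created if needed).
#' @return (invisibly) list with the stage results: `responses`,
#'   `judgments`, `power_fits`, `dprime`, `fits`, and `files` (paths
#'   written).
#' @export
run_pipeline <- function(config, out_dir) {
  if (!inherits(config, "av_config")) stop("config must come from run_config()")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(c(paste("stage:", name), paste("error:", conditionMessage(e))),
                 file.path(out_dir, "FAILED"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  files <- character()

  responses <- stage("simulate", {
    r <- simulate_coincidence_responses(config$design, config$observer)
    validate_responses(r)
    r
  })
  files["responses"] <- write_table(responses, out_dir, "responses.csv")
  judgments <- stage("simulate", {
    j <- simulate_absolute_judgments(config$design, config$observer)
    validate_judgments(j)
    j
  })
  files["absolute"] <- write_table(judgments, out_dir, "absolute.csv")

  power_fits <- stage("power-fits", fit_power_table(judgments))
  files["powerfits"] <- write_table(power_fits, out_dir, "powerfits.csv")

  dprime <- stage("dprime", {
    if (config$bootstrap_B > 0)
      bootstrap_dprime(responses, B = config$bootstrap_B,
                       seed = config$seed)
    else
      empirical_dprime(responses)
  })
  files["dprime"] <- write_table(dprime, out_dir, "dprime.csv")

  fits <- stage("model-fits", {
    af <- as.list(power_fits[power_fits$modality == "aud", c("k", "a")])
    vf <- as.list(power_fits[power_fits$modality == "vis", c("k", "a")])
    compare_models(dprime, aud_fit = af, vis_fit = vf,
                   n_params = config$n_params, variants = config$variants,
                   aud_factor = config$aud_factor,
                   vis_factor = config$vis_factor,
                   reference_distance_m = config$reference_distance_m,
                   printed_formula = config$printed_formula)
  })
  files["fits"] <- write_table(fits, out_dir, "fits.csv")

  comparison <- stage("comparison", {
    fits[order(fits$visual_m, fits$rms_error),
         c("visual_m", "model", "n_params", "scope", "rms_error")]
  })
  files["comparison"] <- write_table(comparison, out_dir, "comparison.csv")

  stage("manifest", {
    cfg_path <- file.path(out_dir, "config.yaml")
    yaml::write_yaml(serialize_config(config), cfg_path)
    files["config"] <- cfg_path
    md5 <- tools::md5sum(unname(files))
    writeLines(c(
      paste0("package: avcapture ",
             as.character(utils::packageVersion("avcapture"))),
      paste0("seed: ", config$seed),
      paste0("config_md5: ", unname(tools::md5sum(cfg_path))),
      paste0(basename(names(md5)), ": ", unname(md5))),
      file.path(out_dir, "manifest.txt"))
  })

  invisible(list(responses = responses, judgments = judgments,
                 power_fits = power_fits, dprime = dprime, fits = fits,
                 files = files))
}

# flatten a config into plain lists for YAML round-tripping
serialize_config <- function(config) {
  list(
    design = list(
      visual_targets = config$design$visual_targets,
      auditory_grids = lapply(config$design$auditory_grids, identity),
      trials_per_stimulus = config$design$trials_per_stimulus,
      n_subjects = config$design$n_subjects,
      absolute_auditory = config$design$absolute_auditory,
      absolute_visual = config$design$absolute_visual),
    observer = unclass(config$observer),
    fitting = list(variants = config$variants, n_params = config$n_params,
                   bootstrap_B = config$bootstrap_B,
                   aud_factor = config$aud_factor,
                   vis_factor = config$vis_factor,
                   reference_distance_m = config$reference_distance_m,
                   printed_formula = config$printed_formula),
    seed = config$seed)
}
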