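#' Pipeline configuration
#'
#' Assembles and validates the configuration for [run_pipeline()]. Because
#' every option is a named argument, unknown keys are rejected before any
#' computation, both here and when loading from YAML.
#'
#' @param gradient gradient stressor name.
#' @param curve a [true_curve_spec()] for the synthetic stage.
#' @param design a [plate_design()].
#' @param noise a [noise_spec()]; its seed is overridden by `seed`.
#' @param seed integer seed governing every random draw in the run.
#' @param use_od_stage simulate OD trajectories and refit growth rates
#'   (`TRUE`), or feed the generated rate table directly to the curve stage.
#' @param no_growth_threshold passed to [rates_from_plate()].
#' @param null_models null models to evaluate.
#' @param zero_zero_additive,ci_multiplier passed to
#'   [interactions_along_gradient()].
#' @param gompertz list of shared Gompertz parameters for the OD simulation:
#'   `lag` (h), `asymptote` (log units), `od0`.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(gradient = "temperature",
                            curve = default_curve_spec(gradient),
                            design = default_plate_design(gradient),
                            noise = noise_spec(),
                            seed = 1L,
                            use_od_stage = TRUE,
                            no_growth_threshold = 0.05,
                            null_models = c("additive", "multiplicative"),
                            zero_zero_additive = TRUE,
                            ci_multiplier = 1.96,
                            gompertz = list(lag = 2, asymptote = 3, od0 = 0.05)) {
  stopifnot(inherits(curve, "true_curve_spec"), inherits(design, "plate_design"),
            inherits(noise, "noise_spec"))
  null_models <- match.arg(null_models, c("additive", "multiplicative"),
                           several.ok = TRUE)
  extra <- setdiff(names(gompertz), c("lag", "asymptote", "od0"))
  if (length(extra))
    stop("unknown gompertz option(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  noise$seed <- as.integer(seed)
  cfg <- list(gradient = gradient, curve = curve, design = design,
              noise = noise, seed = as.integer(seed),
              use_od_stage = isTRUE(use_od_stage),
              no_growth_threshold = no_growth_threshold,
              null_models = null_models,
              zero_zero_additive = isTRUE(zero_zero_additive),
              ci_multiplier = ci_multiplier, gompertz = gompertz)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file whose top level holds [pipeline_config()] options, with
#' `curve`, `design` and `noise` given as nested blocks of the respective
#' constructor arguments. Unknown keys at any of these levels raise a schema
#' error before any stage runs.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  check_keys <- function(x, allowed, what) {
    extra <- setdiff(names(x), allowed)
    if (length(extra))
      stop("unknown ", what, " key(s): ", paste(extra, collapse = ", "),
           call. = FALSE)
  }
  check_keys(raw, names(formals(pipeline_config)), "config")
  args <- raw
  if (!is.null(raw$curve)) {
    check_keys(raw$curve, names(formals(true_curve_spec)), "curve")
    args$curve <- do.call(true_curve_spec, raw$curve)
  }
  if (!is.null(raw$design)) {
    check_keys(raw$design, names(formals(plate_design)), "design")
    args$design <- do.call(plate_design, raw$design)
  }
  if (!is.null(raw$noise)) {
    check_keys(raw$noise, names(formals(noise_spec)), "noise")
    args$noise <- do.call(noise_spec, raw$noise)
  }
  do.call(pipeline_config, args)
}

write_stage_csv <- function(df, out_dir, name) {
  path <- file.path(out_dir, name)
  write.csv(df, path, row.names = FALSE)
  path
}

scenario_from_combo <- function(combo, control_level) {
  stressor_scenario(
    combined_combo = combo,
    single_combos = strsplit(combo, " x ", fixed = TRUE)[[1]],
    control_combo = "control",
    control_level = control_level)
}

#' Run the full analysis pipeline
#'
#' Executes synthesize (optional OD simulation) -> growth-rate extraction ->
#' performance-curve model selection -> null-model interaction
#' classification -> effect-size trend and divergence analysis, writing one
#' CSV per stage plus a `manifest.yaml` recording versions, seed, row counts
#' and file checksums, so that two runs with the same configuration are
#' bit-comparable. On a stage failure, partial outputs are moved under
#' `failed/` and the error names the stage.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("stressorcurves")),
                   r_version = paste(R.version$major, R.version$minor, sep = "."),
                   seed = config$seed, gradient = config$gradient,
                   stages = list())
  files <- character()

  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      failed_dir <- file.path(out_dir, "failed")
      dir.create(failed_dir, showWarnings = FALSE)
      for (f in files) if (file.exists(f))
        file.rename(f, file.path(failed_dir, basename(f)))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # -- synthesize ------------------------------------------------------
  rates <- run_stage("synthesize", function() {
    if (config$use_od_stage) {
      plate <- generate_plate_od(config$curve, config$design, config$noise,
                                 lag = config$gompertz$lag,
                                 asymptote = config$gompertz$asymptote,
                                 od0 = config$gompertz$od0)
      files <<- c(files, write_stage_csv(plate$od, out_dir, "od.csv"))
      manifest$stages$synthesize <<- list(od_rows = nrow(plate$od))
      plate$od
    } else {
      tab <- generate_rate_table(config$curve, config$design, config$noise)
      manifest$stages$synthesize <<- list(rate_rows = nrow(tab))
      tab
    }
  })

  # -- fit-growth ------------------------------------------------------
  rates <- run_stage("fit-growth", function() {
    if (config$use_od_stage) {
      rec <- rates_from_plate(rates,
                              no_growth_threshold = config$no_growth_threshold)
      files <<- c(files,
                  write_stage_csv(rec[c("taxon", "gradient", "stress_combo",
                                        "level", "replicate", "growth_rate")],
                                  out_dir, "rates.csv"),
                  write_stage_csv(rec[c("taxon", "stress_combo", "level",
                                        "replicate", "converged", "no_growth",
                                        "rss")],
                                  out_dir, "growth_qc.csv"))
      manifest$stages$fit_growth <<- list(
        wells = nrow(rec), converged = sum(rec$converged),
        no_growth = sum(rec$no_growth))
      rec
    } else {
      files <<- c(files, write_stage_csv(rates, out_dir, "rates.csv"))
      manifest$stages$fit_growth <<- list(wells = nrow(rates),
                                          converged = nrow(rates),
                                          no_growth = sum(rates$growth_rate == 0))
      rates
    }
  })

  # -- fit-curves ------------------------------------------------------
  sel <- run_stage("fit-curves", function() {
    sel <- select_model(rates)
    files <<- c(files, write_stage_csv(sel$ranking, out_dir,
                                       "model_ranking.csv"))
    co <- coef(sel$best)
    co <- cbind(condition = rownames(co), co)
    files <<- c(files, write_stage_csv(co, out_dir, "coefficients.csv"))
    contrasts <- do.call(rbind, lapply(
      c("intercept", "linear", "quadratic"), function(cf)
        tryCatch(pairwise_contrasts(sel$best, cf), error = function(e) NULL)))
    if (!is.null(contrasts))
      files <<- c(files, write_stage_csv(contrasts, out_dir, "contrasts.csv"))
    grid <- seq(min(sel$best$basis$reference), max(sel$best$basis$reference),
                length.out = 50)
    preds <- do.call(rbind, lapply(sel$best$conditions, function(cond)
      predict(sel$best, condition = cond, x = grid)))
    files <<- c(files, write_stage_csv(preds, out_dir,
                                       "curve_predictions.csv"))
    manifest$stages$fit_curves <<- list(
      best_model = sel$ranking$model[1], aicc = sel$ranking$AICc[1],
      n_candidates = nrow(sel$ranking))
    sel
  })

  # -- interactions ----------------------------------------------------
  effects <- run_stage("interactions", function() {
    combos <- setdiff(config$design$stress_combos, "control")
    eff <- do.call(rbind, lapply(combos, function(cb)
      interactions_along_gradient(
        rates, scenario_from_combo(cb, config$design$control_level),
        null_models = config$null_models,
        ci_multiplier = config$ci_multiplier,
        zero_zero_additive = config$zero_zero_additive)))
    freq <- interaction_frequencies(eff)
    files <<- c(files,
                write_stage_csv(eff, out_dir, "effects.csv"),
                write_stage_csv(freq, out_dir, "frequencies.csv"))
    manifest$stages$interactions <<- list(
      effects = sum(!eff$excluded), excluded = sum(eff$excluded))
    eff
  })

  # -- trends ----------------------------------------------------------
  run_stage("trends", function() {
    combos <- setdiff(config$design$stress_combos, "control")
    rankings <- list(); fits <- list(); divs <- list()
    for (cb in combos) {
      eff_cb <- effects[effects$stress_combo == cb &
                          effects$null_model == "additive", ]
      ts <- tryCatch(select_trend_model(eff_cb), error = function(e) NULL)
      if (!is.null(ts)) {
        r <- ts$ranking; r$stress_combo <- cb
        rankings[[cb]] <- r
        f <- ts$best$fitted; f$stress_combo <- cb
        f$model <- ts$best$structure
        fits[[cb]] <- f
      }
      d <- curve_divergence(sel$best, stressor_condition = cb,
                            effects = effects)
      d$stress_combo <- cb
      divs[[cb]] <- d
    }
    files <<- c(files,
                write_stage_csv(do.call(rbind, rankings), out_dir,
                                "trend_ranking.csv"),
                write_stage_csv(do.call(rbind, fits), out_dir,
                                "trend_fits.csv"),
                write_stage_csv(do.call(rbind, divs), out_dir,
                                "divergence.csv"))
    div_all <- do.call(rbind, divs)
    reg <- tryCatch(divergence_effect_regression(div_all),
                    error = function(e) NULL)
    manifest$stages$trends <<- list(
      combos = length(combos),
      divergence_slope = if (!is.null(reg)) reg$slope else NA,
      divergence_r_squared = if (!is.null(reg)) reg$r_squared else NA)
    NULL
  })

  manifest$files <- as.list(tools::md5sum(sort(files[file.exists(files)])))
  names(manifest$files) <- basename(names(manifest$files))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}

#' Load a locally downloaded deposited-data archive table
#'
#' Maps a user-downloaded growth-rate table (e.g. from the study's deposited
#' archive) into the package's internal long format. The mapping is
#' schema-driven: `column_map` names internal columns and gives the
#' corresponding columns in the file, so renamed layouts can be loaded
#' without editing the file.
#'
#' @param path CSV file on disk (never downloaded by the package).
#' @param column_map named character vector mapping internal names
#'   (`taxon`, `stress_combo`, `level`, `replicate`, `growth_rate`,
#'   optionally `gradient`) to the file's column names. Defaults to the
#'   identity mapping.
#' @return growth-rate data.frame in internal format.
#' @export
load_deposited_archive <- function(path, column_map = NULL) {
  if (!file.exists(path))
    stop("archive file not found: ", path, call. = FALSE)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("taxon", "stress_combo", "level", "replicate", "growth_rate")
  map <- setNames(required, required)
  map["gradient"] <- "gradient"
  if (!is.null(column_map)) map[names(column_map)] <- column_map
  have <- map[map %in% names(raw)]
  missing_cols <- setdiff(required, names(have))
  if (length(missing_cols))
    stop("unrecognized archive layout; expected columns (after mapping): ",
         paste(map[required], collapse = ", "),
         "; missing: ", paste(map[missing_cols], collapse = ", "),
         call. = FALSE)
  out <- data.frame(taxon = as.character(raw[[have["taxon"]]]),
                    gradient = if ("gradient" %in% names(have))
                      raw[[have["gradient"]]] else "unknown",
                    stress_combo = as.character(raw[[have["stress_combo"]]]),
                    level = as.numeric(raw[[have["level"]]]),
                    replicate = raw[[have["replicate"]]],
                    growth_rate = as.numeric(raw[[have["growth_rate"]]]),
                    stringsAsFactors = FALSE)
  out
}
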