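#' Ground-truth performance-curve specification
#'
#' Defines the "true" unimodal performance curve used by the synthetic plate
#' generator, parameterized directly by the quantities the downstream analysis
#' interprets: curve height (`r_max`, the peak growth rate), position (`x_opt`,
#' the gradient value of the peak) and width (`w`, the distance from the peak
#' to the zero crossing). Each added stressor modifies the curve additively
#' through `delta_height`, `delta_position` and `delta_width`, and taxa deviate
#' from the shared curve through Gaussian deviations with standard deviations
#' `taxon_sd`.
#'
#' The curve itself is a downward parabola clamped at zero:
#' \deqn{r(x) = \max\{0,\; r_{eff} (1 - ((x - x_{opt,eff})/w_{eff})^2)\}}
#' where each effective parameter is the base value plus the taxon deviation
#' plus `n_added_stressors` times its delta.
#'
#' @param r_max peak growth rate (per hour), >= 0.
#' @param x_opt gradient value of the peak (gradient units).
#' @param w half-width: distance from peak to zero crossing (> 0).
#' @param delta_height,delta_position,delta_width additive modification of
#'   (`r_max`, `x_opt`, `w`) per added stressor.
#' @param taxon_sd length-3 numeric: standard deviations of taxon-level
#'   deviations for (`r_max`, `x_opt`, `w`).
#' @return An object of class `true_curve_spec`.
#' @seealso [true_rate()], [generate_rate_table()]
#' @export
true_curve_spec <- function(r_max, x_opt, w,
                            delta_height = 0, delta_position = 0,
                            delta_width = 0, taxon_sd = c(0, 0, 0)) {
  if (!is.numeric(r_max) || length(r_max) != 1L || r_max < 0)
    stop("'r_max' must be a single non-negative number", call. = FALSE)
  if (!is.numeric(w) || length(w) != 1L || w <= 0)
    stop("'w' must be a single positive number", call. = FALSE)
  if (length(taxon_sd) != 3L || any(taxon_sd < 0))
    stop("'taxon_sd' must be three non-negative standard deviations", call. = FALSE)
  structure(
    list(r_max = r_max, x_opt = x_opt, w = w,
         delta_height = delta_height, delta_position = delta_position,
         delta_width = delta_width, taxon_sd = as.numeric(taxon_sd)),
    class = "true_curve_spec")
}

#' Plate experimental design
#'
#' Describes the factorial layout of a gradient experiment: which taxa are
#' assayed, the ordered gradient levels, the stressor combinations (a control,
#' single added stressors and their pairwise combination), the number of
#' replicate wells per condition, which gradient level serves as the control
#' baseline, and the OD sampling schedule.
#'
#' @param taxa character vector of taxon identifiers.
#' @param gradient name of the gradient stressor (e.g. `"temperature"`).
#' @param gradient_levels strictly increasing numeric gradient values.
#' @param stress_combos condition labels; `"control"` plus added-stressor
#'   labels, two-stressor combinations written `"B x C"`.
#' @param replicates wells per taxon x condition (>= 2).
#' @param control_level the gradient value used as baseline; must be one of
#'   `gradient_levels`.
#' @param sampling_times hours at which OD600 is recorded.
#' @return An object of class `plate_design`.
#' @export
plate_design <- function(taxa, gradient, gradient_levels, stress_combos,
                         replicates = 3,
                         control_level = gradient_levels[1],
                         sampling_times = default_sampling_times()) {
  if (replicates < 2) stop("'replicates' must be >= 2", call. = FALSE)
  if (any(diff(gradient_levels) <= 0))
    stop("'gradient_levels' must be strictly increasing", call. = FALSE)
  if (!control_level %in% gradient_levels)
    stop("'control_level' must be one of 'gradient_levels'", call. = FALSE)
  if (!"control" %in% stress_combos)
    stop("'stress_combos' must include \"control\"", call. = FALSE)
  structure(
    list(taxa = as.character(taxa), gradient = gradient,
         gradient_levels = as.numeric(gradient_levels),
         stress_combos = as.character(stress_combos),
         replicates = as.integer(replicates),
         control_level = control_level,
         sampling_times = as.numeric(sampling_times)),
    class = "plate_design")
}

#' Noise specification for the synthetic generator
#'
#' @param od_sd multiplicative log-scale noise sd on OD readings (>= 0).
#' @param rate_sd Gaussian residual sd on replicate growth rates (>= 0).
#' @param seed integer RNG seed; identical seeds give identical datasets.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(od_sd = 0.02, rate_sd = 0.05, seed = 1L) {
  if (od_sd < 0 || rate_sd < 0)
    stop("noise standard deviations must be non-negative", call. = FALSE)
  structure(list(od_sd = od_sd, rate_sd = rate_sd, seed = as.integer(seed)),
            class = "noise_spec")
}

#' @export
print.true_curve_spec <- function(x, ...) {
  cat("True performance curve: r_max =", x$r_max, "/h at", x$x_opt,
      "; half-width", x$w, "\n")
  cat("  per added stressor: height", x$delta_height,
      ", position", x$delta_position, ", width", x$delta_width, "\n")
  cat("  taxon sd (height, position, width):",
      paste(x$taxon_sd, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.plate_design <- function(x, ...) {
  cat("Plate design:", length(x$taxa), "taxa x",
      length(x$stress_combos), "conditions x",
      length(x$gradient_levels), x$gradient, "levels x",
      x$replicates, "replicates\n")
  cat("  levels:", paste(x$gradient_levels, collapse = ", "),
      "(control at", x$control_level, ")\n")
  invisible(x)
}

#' Default OD sampling schedule
#'
#' Readings every 2 h for the first 12 h of incubation, then every 4 h until
#' 36 h, by which time the cultures modelled here have reached carrying
#' capacity.
#'
#' @return numeric vector of hours.
#' @export
default_sampling_times <- function() c(seq(0, 12, by = 2), seq(16, 36, by = 4))

#' Default ground-truth curve and plate design for each gradient
#'
#' Study-style defaults: 12 taxa, 3 replicates, a control plus two single
#' added stressors and their combination, and gradient levels spanning nine
#' temperatures (15-47 C, control 20 C), eight pH levels (4-11, control 7.2)
#' or eight salinities (0-35 g NaCl/L, control 0).
#'
#' @param gradient one of `"temperature"`, `"pH"`, `"salinity"`.
#' @param n_taxa number of taxa (default 12).
#' @param replicates replicate wells per condition (default 3).
#' @return `default_plate_design()` returns a [plate_design()];
#'   `default_curve_spec()` returns a [true_curve_spec()].
#' @export
default_plate_design <- function(gradient = c("temperature", "pH", "salinity"),
                                 n_taxa = 12, replicates = 3) {
  gradient <- match.arg(gradient)
  levels <- switch(gradient,
    temperature = c(15, 20, 24, 28, 32, 36, 40, 44, 47),
    pH          = c(4, 5, 6, 7.2, 8, 9, 10, 11),
    salinity    = c(0, 5, 10, 15, 20, 25, 30, 35))
  control <- switch(gradient, temperature = 20, pH = 7.2, salinity = 0)
  combos <- switch(gradient,
    temperature = c("control", "pH", "salinity", "pH x salinity"),
    pH          = c("control", "salinity", "temperature", "salinity x temperature"),
    salinity    = c("control", "temperature", "pH", "pH x temperature"))
  plate_design(taxa = sprintf("taxon_%02d", seq_len(n_taxa)),
               gradient = gradient, gradient_levels = levels,
               stress_combos = combos, replicates = replicates,
               control_level = control)
}

#' @rdname default_plate_design
#' @export
default_curve_spec <- function(gradient = c("temperature", "pH", "salinity")) {
  gradient <- match.arg(gradient)
  switch(gradient,
    temperature = true_curve_spec(r_max = 1.2, x_opt = 27, w = 17,
                                  delta_height = -0.25, delta_position = 2,
                                  delta_width = -1.5,
                                  taxon_sd = c(0.12, 2, 1.5)),
    pH          = true_curve_spec(r_max = 1.2, x_opt = 7.5, w = 3.5,
                                  delta_height = -0.25, delta_position = 0.4,
                                  delta_width = -0.3,
                                  taxon_sd = c(0.12, 0.4, 0.3)),
    salinity    = true_curve_spec(r_max = 1.2, x_opt = 8, w = 25,
                                  delta_height = -0.25, delta_position = -2,
                                  delta_width = -2,
                                  taxon_sd = c(0.12, 2, 2)))
}

n_added_stressors <- function(combo) {
  ifelse(combo == "control", 0L,
         lengths(strsplit(as.character(combo), " x ", fixed = TRUE)))
}

#' True growth rate on the ground-truth curve
#'
#' Evaluates the clamped-parabola performance curve at gradient value `x`,
#' after applying `n_added_stressors` copies of the per-stressor deltas and a
#' taxon-level deviation `taxon_deviation = c(d_height, d_position, d_width)`.
#'
#' @param spec a [true_curve_spec()].
#' @param x gradient value(s).
#' @param n_added_stressors how many additional stressors are present.
#' @param taxon_deviation length-3 deviation of (height, position, width).
#' @return growth rate(s) per hour, never negative.
#' @examples
#' sp <- true_curve_spec(r_max = 1, x_opt = 25, w = 10)
#' true_rate(sp, 25)            # the peak: 1
#' true_rate(sp, c(15, 35))     # zero crossings
#' @export
true_rate <- function(spec, x, n_added_stressors = 0,
                      taxon_deviation = c(0, 0, 0)) {
  stopifnot(inherits(spec, "true_curve_spec"), length(taxon_deviation) == 3L)
  r_eff <- spec$r_max + taxon_deviation[1] + n_added_stressors * spec$delta_height
  x_eff <- spec$x_opt + taxon_deviation[2] + n_added_stressors * spec$delta_position
  w_eff <- spec$w + taxon_deviation[3] + n_added_stressors * spec$delta_width
  if (w_eff <= 0)
    stop("effective curve width is not positive; invalid specification",
         call. = FALSE)
  r_eff <- max(r_eff, 0)
  pmax(0, r_eff * (1 - ((x - x_eff) / w_eff)^2))
}

draw_taxon_deviations <- function(spec, taxa) {
  dev <- cbind(height = rnorm(length(taxa), 0, spec$taxon_sd[1]),
               position = rnorm(length(taxa), 0, spec$taxon_sd[2]),
               width = rnorm(length(taxa), 0, spec$taxon_sd[3]))
  rownames(dev) <- taxa
  dev
}

#' Generate a synthetic growth-rate table
#'
#' Produces one `GrowthRateRecord` row per taxon x stressor combination x
#' gradient level x replicate. Taxon-level deviations of (height, position,
#' width) are drawn once per taxon and reused across all conditions; replicate
#' rates are the true curve value plus Gaussian noise (`rate_sd`), floored at
#' zero because growth rate cannot be negative.
#'
#' @param spec a [true_curve_spec()].
#' @param design a [plate_design()].
#' @param noise a [noise_spec()]; `noise$seed` makes the table reproducible.
#' @return data.frame with columns `taxon`, `gradient`, `stress_combo`,
#'   `level`, `replicate`, `growth_rate`, plus a `"taxon_deviations"`
#'   attribute holding the drawn deviations.
#' @examples
#' tab <- generate_rate_table(default_curve_spec(), default_plate_design(),
#'                            noise_spec(seed = 42))
#' nrow(tab)  # 12 * 4 * 9 * 3
#' @export
generate_rate_table <- function(spec, design, noise = noise_spec()) {
  stopifnot(inherits(spec, "true_curve_spec"), inherits(design, "plate_design"),
            inherits(noise, "noise_spec"))
  set.seed(noise$seed)
  dev <- draw_taxon_deviations(spec, design$taxa)
  grid <- expand.grid(replicate = seq_len(design$replicates),
                      level = design$gradient_levels,
                      stress_combo = design$stress_combos,
                      taxon = design$taxa,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("taxon", "stress_combo", "level", "replicate")]
  n_add <- n_added_stressors(grid$stress_combo)
  truth <- vapply(seq_len(nrow(grid)), function(i) {
    true_rate(spec, grid$level[i], n_add[i], dev[grid$taxon[i], ])
  }, numeric(1))
  rate <- pmax(0, truth + rnorm(nrow(grid), 0, noise$rate_sd))
  out <- data.frame(taxon = grid$taxon, gradient = design$gradient,
                    stress_combo = grid$stress_combo, level = grid$level,
                    replicate = grid$replicate, growth_rate = rate,
                    stringsAsFactors = FALSE)
  attr(out, "taxon_deviations") <- dev
  attr(out, "true_rate") <- truth
  out
}

#' Generate a Gompertz OD600 time series
#'
#' Simulates one well's biomass trajectory under the same Gompertz
#' parameterization that [fit_gompertz()] fits (see [gompertz_log_growth()]):
#' `OD(t) = od0 * exp(y(t)) * exp(noise)` with `y(t)` the Gompertz log
#' fold-change. A zero growth rate yields a flat series at `od0`.
#'
#' @param rate maximum specific growth rate mu_max (per hour, >= 0).
#' @param lag lag time lambda (hours).
#' @param asymptote Gompertz asymptote A (natural-log units of fold change).
#' @param od0 starting OD600 (> 0).
#' @param times sampling times (hours); must be non-empty.
#' @param od_sd multiplicative log-scale noise sd (0 = noiseless).
#' @return An `od_timeseries`: list with `times` and `od`.
#' @export
generate_od_timeseries <- function(rate, lag = 2, asymptote = 3, od0 = 0.05,
                                   times = default_sampling_times(),
                                   od_sd = 0) {
  if (length(times) == 0L) stop("'times' must be non-empty", call. = FALSE)
  stopifnot(rate >= 0, asymptote > 0, od0 > 0)
  y <- if (rate == 0) rep(0, length(times))
       else gompertz_log_growth(times, mu_max = rate, lag = lag, A = asymptote)
  od <- od0 * exp(y) * exp(rnorm(length(times), 0, od_sd))
  structure(list(times = as.numeric(times), od = od), class = "od_timeseries")
}

#' Generate a full plate of synthetic OD600 trajectories
#'
#' Draws per-well growth rates exactly as [generate_rate_table()] does (same
#' seed, same table), then simulates one OD time series per well so that the
#' growth-fitting stage can be exercised end to end against known rates.
#'
#' @inheritParams generate_rate_table
#' @param lag,asymptote,od0 Gompertz parameters shared by all wells.
#' @return list with `od`: long data.frame (`taxon`, `gradient`,
#'   `stress_combo`, `level`, `replicate`, `time_h`, `od600`) and
#'   `true_rates`: the matching rate table.
#' @export
generate_plate_od <- function(spec, design, noise = noise_spec(),
                              lag = 2, asymptote = 3, od0 = 0.05) {
  rates <- generate_rate_table(spec, design, noise)
  per_well <- lapply(seq_len(nrow(rates)), function(i) {
    ts <- generate_od_timeseries(rates$growth_rate[i], lag = lag,
                                 asymptote = asymptote, od0 = od0,
                                 times = design$sampling_times,
                                 od_sd = noise$od_sd)
    data.frame(taxon = rates$taxon[i], gradient = rates$gradient[i],
               stress_combo = rates$stress_combo[i], level = rates$level[i],
               replicate = rates$replicate[i], time_h = ts$times,
               od600 = ts$od, stringsAsFactors = FALSE)
  })
  list(od = do.call(rbind, per_well), true_rates = rates)
}
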