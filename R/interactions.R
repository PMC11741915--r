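#' Additive null-model prediction of combined-stressor growth
#'
#' Predicts the growth rate under combined stressors as the sum of the
#' single-stressor effects relative to the control baseline:
#' `G_AB = (G_As - G_Ac) + (G_Bc - G_Ac) + G_Ac`, i.e.
#' `G_As + G_Bc - G_Ac`. With a third stressor, `G_Cc - G_Ac` is added.
#' Because growth rate cannot be negative, predictions below zero are set to
#' zero; this avoids a bias towards antagonism at high stress intensities
#' where single stressors are already strongly detrimental.
#'
#' @param G_Ac mean growth in control conditions of the gradient stressor A.
#' @param G_As mean growth under stressor A at gradient level s.
#' @param G_Bc mean growth under added stressor B at A's control level.
#' @param G_Cc optional mean growth under a second added stressor C at A's
#'   control level (three-way prediction).
#' @return predicted combined growth rate (clamped at zero).
#' @examples
#' additive_prediction(G_Ac = 1.0, G_As = 0.6, G_Bc = 0.7)        # 0.3
#' additive_prediction(G_Ac = 1.0, G_As = 0.1, G_Bc = 0.2)        # clamped to 0
#' additive_prediction(G_Ac = 1.0, G_As = 0.6, G_Bc = 0.7, G_Cc = 0.8)  # 0.1
#' @export
additive_prediction <- function(G_Ac, G_As, G_Bc, G_Cc = NULL) {
  if (missing(G_Ac) || missing(G_As) || missing(G_Bc) ||
      is.null(G_Ac) || is.null(G_As) || is.null(G_Bc))
    stop("additive prediction requires G_Ac, G_As and G_Bc", call. = FALSE)
  pred <- G_As + G_Bc - G_Ac
  if (!is.null(G_Cc)) pred <- pred + (G_Cc - G_Ac)
  max(0, pred)
}

#' Multiplicative null-model prediction of combined-stressor growth
#'
#' Predicts the combined growth rate as the product of proportional
#' single-stressor effects:
#' `G_AB = G_Ac * (G_As/G_Ac) * (G_Bc/G_Ac) [* (G_Cc/G_Ac)]`.
#' Non-negative by construction when all inputs are non-negative.
#'
#' @inheritParams additive_prediction
#' @return predicted combined growth rate.
#' @export
multiplicative_prediction <- function(G_Ac, G_As, G_Bc, G_Cc = NULL) {
  if (missing(G_Ac) || missing(G_As) || missing(G_Bc) ||
      is.null(G_Ac) || is.null(G_As) || is.null(G_Bc))
    stop("multiplicative prediction requires G_Ac, G_As and G_Bc",
         call. = FALSE)
  if (G_Ac == 0)
    stop("control growth G_Ac is zero; multiplicative prediction undefined",
         call. = FALSE)
  pred <- G_Ac * (G_As / G_Ac) * (G_Bc / G_Ac)
  if (!is.null(G_Cc)) pred <- pred * (G_Cc / G_Ac)
  pred
}

#' Summary statistics of one replicate group
#'
#' @param x replicate growth rates.
#' @return list with `mean`, `sd`, `n`.
#' @export
group_stats <- function(x) {
  x <- x[is.finite(x)]
  list(mean = mean(x), sd = if (length(x) > 1) sd(x) else NA_real_,
       n = length(x))
}

#' Bias-corrected Hedge's d between null prediction and observation
#'
#' Standardised mean difference between the null-model predicted group and
#' the observed combined-stressor group, with Hedges' small-sample bias
#' correction:
#' \deqn{d = J \cdot \frac{\bar{x}_{pred} - \bar{x}_{obs}}{s_{pooled}},\quad
#'       J = 1 - \frac{3}{4(n_{obs}+n_{pred}-2) - 1}}
#' \deqn{\mathrm{var}(d) = \frac{n_{obs}+n_{pred}}{n_{obs} n_{pred}} +
#'       \frac{d^2}{2(n_{obs}+n_{pred})}}
#' with the 95% CI `d +/- 1.96 sqrt(var(d))`. The sign convention makes
#' positive d a combined effect *more* detrimental than the null prediction
#' (observed below predicted), i.e. synergism for performance measures where
#' all stressors reduce growth.
#'
#' @param observed observed combined-stressor group: list with `mean`, `sd`,
#'   `n` (see [group_stats()]).
#' @param predicted null-prediction group: list with `mean`, `sd`, `n`,
#'   where `sd` is the pseudo standard deviation back-formed from the
#'   variance of the prediction (see [interactions_along_gradient()]).
#' @param ci_multiplier normal-approximation CI multiplier (default 1.96).
#' @return list with `d`, `var_d`, `ci` (length 2), `J`, `s_pooled`.
#' @examples
#' obs <- group_stats(c(0.30, 0.35, 0.40))
#' pred <- group_stats(c(0.50, 0.55, 0.60))
#' hedges_d(obs, pred)$d   # 3.2
#' @export
hedges_d <- function(observed, predicted, ci_multiplier = 1.96) {
  n_o <- observed$n; n_p <- predicted$n
  if (n_o < 2 || n_p < 2)
    stop("both groups need n >= 2", call. = FALSE)
  s_pooled <- sqrt(((n_o - 1) * observed$sd^2 + (n_p - 1) * predicted$sd^2) /
                     (n_o + n_p - 2))
  if (!is.finite(s_pooled) || s_pooled == 0)
    stop("pooled standard deviation is zero; Hedge's d undefined",
         call. = FALSE)
  J <- 1 - 3 / (4 * (n_o + n_p - 2) - 1)
  d <- J * (predicted$mean - observed$mean) / s_pooled
  var_d <- (n_o + n_p) / (n_o * n_p) + d^2 / (2 * (n_o + n_p))
  ci <- d + c(-1, 1) * ci_multiplier * sqrt(var_d)
  list(d = d, var_d = var_d, ci = ci, J = J, s_pooled = s_pooled)
}

#' Classify a stressor interaction from Hedge's d and its CI
#'
#' Confidence intervals crossing zero are classed additive; otherwise the
#' sign of d decides: negative d is antagonistic (combined effect less
#' detrimental than predicted), positive d synergistic (more detrimental).
#'
#' @param d Hedge's d.
#' @param ci length-2 confidence interval.
#' @return `"additive"`, `"antagonistic"` or `"synergistic"`.
#' @export
classify_interaction <- function(d, ci) {
  if (ci[1] <= 0 && ci[2] >= 0) return("additive")
  if (d < 0) "antagonistic" else "synergistic"
}

#' Describe a stressor scenario for interaction assessment
#'
#' Names the conditions in a rate table that play each role in the null
#' models: the control condition along gradient stressor A, the single
#' added-stressor condition(s) measured at A's control level, and the
#' combined condition observed at every gradient level.
#'
#' @param combined_combo label of the combined-stressor condition.
#' @param single_combos labels of the single added-stressor condition(s)
#'   (one for two-way, two for three-way scenarios).
#' @param control_combo label of the no-added-stressor condition.
#' @param control_level gradient value used as control baseline.
#' @return An object of class `stressor_scenario`.
#' @export
stressor_scenario <- function(combined_combo, single_combos,
                              control_combo = "control", control_level) {
  if (!length(single_combos) %in% 1:2)
    stop("'single_combos' must name one or two added stressors", call. = FALSE)
  structure(list(combined_combo = combined_combo,
                 single_combos = as.character(single_combos),
                 control_combo = control_combo,
                 control_level = control_level),
            class = "stressor_scenario")
}

# variance of the predicted mean as a combination of group-mean variances
predicted_group <- function(null_model, g_Ac, g_As, g_Bc, g_Cc = NULL) {
  se2 <- function(g) g$sd^2 / g$n
  if (null_model == "additive") {
    mean_raw <- g_As$mean + g_Bc$mean - g_Ac$mean
    if (!is.null(g_Cc)) mean_raw <- mean_raw + (g_Cc$mean - g_Ac$mean)
    var_mean <- se2(g_As) + se2(g_Bc) + se2(g_Ac) * (if (is.null(g_Cc)) 1 else 4)
    if (!is.null(g_Cc)) var_mean <- var_mean + se2(g_Cc)
    mean_pred <- max(0, mean_raw)
  } else {
    # first-order (delta-method) variance of the product of relative effects
    Ac <- g_Ac$mean; As <- g_As$mean; Bc <- g_Bc$mean
    if (is.null(g_Cc)) {
      mean_pred <- As * Bc / Ac
      grads <- c(As = Bc / Ac, Bc = As / Ac, Ac = -As * Bc / Ac^2)
      var_mean <- grads["As"]^2 * se2(g_As) + grads["Bc"]^2 * se2(g_Bc) +
        grads["Ac"]^2 * se2(g_Ac)
    } else {
      Cc <- g_Cc$mean
      mean_pred <- As * Bc * Cc / Ac^2
      var_mean <- (Bc * Cc / Ac^2)^2 * se2(g_As) +
        (As * Cc / Ac^2)^2 * se2(g_Bc) +
        (As * Bc / Ac^2)^2 * se2(g_Cc) +
        (2 * As * Bc * Cc / Ac^3)^2 * se2(g_Ac)
    }
    var_mean <- as.numeric(var_mean)
  }
  ns <- c(g_As$n, g_Bc$n, g_Ac$n, if (!is.null(g_Cc)) g_Cc$n)
  n_pred <- round(mean(ns))
  list(mean = mean_pred, sd = sqrt(var_mean * n_pred), n = n_pred,
       raw_mean = if (null_model == "additive")
         mean_raw else mean_pred)
}

#' Interaction effect sizes at every level along a gradient
#'
#' For each taxon and each non-control gradient level, extracts the control
#' response `G(A_c)`, the single added-stressor response(s) `G(B_c)` (and
#' `G(C_c)`) at the control level, the gradient-stressor response `G(A_s)`
#' at that level and the observed combined response; computes the null-model
#' prediction, Hedge's d with its CI, and the interaction classification.
#' The control level itself is excluded from assessment.
#'
#' Cells where every replicate shows zero growth and the prediction is also
#' zero carry no standardisable signal; with `zero_zero_additive = TRUE`
#' (default) they are classed additive with d = 0, reflecting that an
#' additive prediction of no growth matches an observation of no growth.
#' Other zero-variance cells are flagged and excluded (with a logged count).
#'
#' @param rates growth-rate table (`taxon`, `stress_combo`, `level`,
#'   `growth_rate`).
#' @param scenario a [stressor_scenario()].
#' @param null_models any of `"additive"`, `"multiplicative"`.
#' @param ci_multiplier CI multiplier for [hedges_d()].
#' @param zero_zero_additive classify zero-prediction / zero-observation
#'   cells as additive instead of excluding them.
#' @return data.frame of interaction effects, one row per taxon x level x
#'   null model, with columns `taxon`, `level`, `null_model`,
#'   `predicted_mean`, `predicted_sd`, `observed_mean`, `observed_sd`,
#'   `n_obs`, `n_pred`, `d`, `var_d`, `ci_lo`, `ci_hi`, `classification`,
#'   `excluded`, `reason`.
#' @export
interactions_along_gradient <- function(rates, scenario,
                                        null_models = c("additive",
                                                        "multiplicative"),
                                        ci_multiplier = 1.96,
                                        zero_zero_additive = TRUE) {
  stopifnot(inherits(scenario, "stressor_scenario"))
  null_models <- match.arg(null_models, several.ok = TRUE)
  if ("converged" %in% names(rates)) rates <- rates[rates$converged, ]

  need <- c(scenario$control_combo, scenario$single_combos,
            scenario$combined_combo)
  missing_combos <- setdiff(need, unique(rates$stress_combo))
  if (length(missing_combos))
    stop("rate table lacks required condition(s): ",
         paste(missing_combos, collapse = ", "), call. = FALSE)

  taxa <- unique(rates$taxon)
  levels_all <- sort(unique(rates$level))
  assess <- setdiff(levels_all, scenario$control_level)
  three_way <- length(scenario$single_combos) == 2

  get_group <- function(taxon, combo, level) {
    v <- rates$growth_rate[rates$taxon == taxon &
                             rates$stress_combo == combo &
                             rates$level == level]
    if (length(v) < 2) return(NULL)
    group_stats(v)
  }

  rows <- list()
  n_excluded <- 0L
  for (taxon in taxa) {
    g_Ac <- get_group(taxon, scenario$control_combo, scenario$control_level)
    g_Bc <- get_group(taxon, scenario$single_combos[1], scenario$control_level)
    g_Cc <- if (three_way)
      get_group(taxon, scenario$single_combos[2], scenario$control_level)
    else NULL
    for (s in assess) {
      g_As <- get_group(taxon, scenario$control_combo, s)
      g_obs <- get_group(taxon, scenario$combined_combo, s)
      base_missing <- is.null(g_Ac) || is.null(g_Bc) || is.null(g_As) ||
        is.null(g_obs) || (three_way && is.null(g_Cc))
      for (nm in null_models) {
        row <- data.frame(taxon = taxon, gradient = rates$gradient[1],
                          stress_combo = scenario$combined_combo,
                          level = s, null_model = nm,
                          predicted_mean = NA_real_, predicted_sd = NA_real_,
                          observed_mean = NA_real_, observed_sd = NA_real_,
                          n_obs = NA_integer_, n_pred = NA_integer_,
                          d = NA_real_, var_d = NA_real_,
                          ci_lo = NA_real_, ci_hi = NA_real_,
                          classification = NA_character_,
                          excluded = TRUE, reason = NA_character_,
                          stringsAsFactors = FALSE)
        if (base_missing) {
          row$reason <- "missing replicate group"
          n_excluded <- n_excluded + 1L
          rows[[length(rows) + 1L]] <- row
          next
        }
        if (nm == "multiplicative" && g_Ac$mean == 0) {
          row$reason <- "zero control mean; multiplicative undefined"
          n_excluded <- n_excluded + 1L
          rows[[length(rows) + 1L]] <- row
          next
        }
        pred <- predicted_group(nm, g_Ac, g_As, g_Bc, g_Cc)
        row$predicted_mean <- pred$mean
        row$predicted_sd <- pred$sd
        row$observed_mean <- g_obs$mean
        row$observed_sd <- g_obs$sd
        row$n_obs <- g_obs$n
        row$n_pred <- pred$n
        hd <- tryCatch(
          hedges_d(g_obs, pred, ci_multiplier = ci_multiplier),
          error = function(e) NULL)
        if (is.null(hd)) {
          if (zero_zero_additive && pred$mean == 0 && g_obs$mean == 0) {
            row$d <- 0
            row$classification <- "additive"
            row$excluded <- FALSE
            row$reason <- "zero growth under both prediction and observation"
          } else {
            row$reason <- "zero pooled variance"
            n_excluded <- n_excluded + 1L
          }
        } else {
          row$d <- hd$d
          row$var_d <- hd$var_d
          row$ci_lo <- hd$ci[1]
          row$ci_hi <- hd$ci[2]
          row$classification <- classify_interaction(hd$d, hd$ci)
          row$excluded <- FALSE
        }
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  if (n_excluded)
    message(n_excluded, " taxon x level cell(s) excluded: ",
            "missing groups or zero pooled variance")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Frequency of interaction types along the gradient
#'
#' Counts each classification per gradient level (and per null model /
#' stressor combination) among taxa with computable effects, plus panel
#' totals across all levels (rows with `level = NA`). Excluded cells are
#' dropped.
#'
#' @param effects output of [interactions_along_gradient()] (several runs
#'   may be row-bound).
#' @return data.frame with columns `null_model`, `stress_combo`, `level`,
#'   `classification`, `n`; totals carry `level = NA`.
#' @export
interaction_frequencies <- function(effects) {
  eff <- effects[!effects$excluded & !is.na(effects$classification), ]
  if (!nrow(eff)) {
    return(data.frame(null_model = character(), stress_combo = character(),
                      level = numeric(), classification = character(),
                      n = integer(), stringsAsFactors = FALSE))
  }
  labs <- c("additive", "antagonistic", "synergistic")
  panels <- split(eff, list(eff$null_model, eff$stress_combo), drop = TRUE)
  out <- do.call(rbind, lapply(panels, function(p) {
    tab <- table(level = p$level,
                 classification = factor(p$classification, levels = labs))
    per <- as.data.frame(tab, stringsAsFactors = FALSE)
    per$level <- as.numeric(per$level)
    tot <- as.data.frame(margin.table(tab, "classification"),
                         stringsAsFactors = FALSE)
    tot$level <- NA_real_
    both <- rbind(per[c("level", "classification", "Freq")],
                  tot[c("level", "classification", "Freq")])
    data.frame(null_model = p$null_model[1], stress_combo = p$stress_combo[1],
               level = both$level, classification = both$classification,
               n = both$Freq, stringsAsFactors = FALSE)
  }))
  out <- out[order(out$null_model, out$stress_combo, out$level), ]
  rownames(out) <- NULL
  out
}
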