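#' Candidate structures for effect-size trend models
#'
#' Hedge's d along a gradient is modelled by penalized cubic regression
#' spline GAMs with one of four structures: `"intercept"` (no trend),
#' `"global"` (one shared smooth), `"global_taxon"` (shared smooth with
#' taxon-specific intercepts) or `"by_taxon"` (taxon-specific smooths, a
#' factor-smooth construction sharing one smoothing parameter, plus taxon
#' intercepts).
#'
#' @return character vector of structure names.
#' @export
trend_candidates <- function() {
  c("intercept", "global", "global_taxon", "by_taxon")
}

trend_formula <- function(structure, k) {
  switch(structure,
    intercept    = d ~ 1,
    global       = stats::as.formula(sprintf("d ~ s(level, bs = 'cs', k = %d)", k)),
    global_taxon = stats::as.formula(
      sprintf("d ~ taxon + s(level, bs = 'cs', k = %d)", k)),
    by_taxon     = stats::as.formula(
      sprintf("d ~ taxon + s(level, taxon, bs = 'fs', k = %d, xt = list(bs = 'cr'))",
              k)),
    stop("unknown trend structure: ", structure, call. = FALSE))
}

prepare_trend_data <- function(effects) {
  eff <- effects[!effects$excluded & is.finite(effects$d), ]
  data.frame(d = eff$d, level = eff$level, taxon = factor(eff$taxon),
             var_d = eff$var_d)
}

#' Fit a penalized-spline trend model of Hedge's d along a gradient
#'
#' Fits Hedge's d as a smooth function of the gradient using cubic
#' regression splines with shrinkage (`bs = "cs"`, and `select = TRUE`), so
#' that the smooth is penalized towards zero when the association with the
#' gradient is weak. Smoothing parameters are estimated by REML. Per-taxon
#' smooths use a factor-smooth basis that shares a single smoothing
#' parameter across taxa, which keeps estimation stable with the 7-8
#' assessable levels per taxon typical of these designs.
#'
#' @param effects interaction-effect table from
#'   [interactions_along_gradient()] (excluded rows are dropped).
#' @param structure one of [trend_candidates()].
#' @param k basis dimension request (default 10, reduced automatically to
#'   the number of distinct gradient levels).
#' @param weight_by_variance weight observations by `1/var_d` (default off:
#'   effect sizes enter unweighted).
#' @return An object of class `trend_fit`: the mgcv model plus `structure`,
#'   `edf_smooth` (summed effective df of smooth terms), `logLik`, `k_eff`,
#'   `n`, `aicc`, and `fitted` (per-observation fit with pointwise 95% CI).
#' @export
fit_trend_model <- function(effects, structure = "global_taxon", k = 10,
                            weight_by_variance = FALSE) {
  structure <- match.arg(structure, trend_candidates())
  df <- prepare_trend_data(effects)
  if (!nrow(df)) stop("no usable effect sizes", call. = FALSE)
  if (structure != "intercept") {
    per_taxon <- tapply(df$level, df$taxon, function(x) length(unique(x)))
    bad <- names(per_taxon)[per_taxon < 5]
    if (length(bad))
      stop("need >= 5 distinct gradient levels per taxon for smooth terms; ",
           "offending taxa: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (var(df$d) < 1e-24) {
    # degenerate constant response: every structure reduces to a flat line
    out <- list(model = NULL, structure = structure, k_basis = NA_integer_,
                edf_smooth = 0, logLik = NA_real_, k_eff = NA_real_,
                n = nrow(df), aicc = NA_real_,
                fitted = data.frame(level = df$level, taxon = df$taxon,
                                    d = df$d, fit = mean(df$d),
                                    ci_lo = mean(df$d), ci_hi = mean(df$d)))
    class(out) <- "trend_fit"
    return(out)
  }
  k_use <- min(k, length(unique(df$level)))
  m <- if (weight_by_variance) {
    df$.w <- 1 / df$var_d
    mgcv::gam(trend_formula(structure, k_use), data = df,
              method = "REML", select = TRUE, weights = .w)
  } else {
    mgcv::gam(trend_formula(structure, k_use), data = df,
              method = "REML", select = TRUE)
  }
  ll <- logLik(m)
  k_eff <- as.numeric(attr(ll, "df"))
  n <- nrow(df)
  pr <- predict(m, se.fit = TRUE)
  fitted <- data.frame(level = df$level, taxon = df$taxon, d = df$d,
                       fit = as.numeric(pr$fit),
                       ci_lo = as.numeric(pr$fit - 1.96 * pr$se.fit),
                       ci_hi = as.numeric(pr$fit + 1.96 * pr$se.fit))
  edf_smooth <- if (length(m$smooth)) {
    sum(vapply(seq_along(m$smooth), function(i) {
      idx <- m$smooth[[i]]$first.para:m$smooth[[i]]$last.para
      sum(m$edf[idx])
    }, numeric(1)))
  } else 0
  out <- list(model = m, structure = structure, k_basis = k_use,
              edf_smooth = edf_smooth, logLik = as.numeric(ll),
              k_eff = k_eff, n = n,
              aicc = aicc(as.numeric(ll), k_eff, n),
              fitted = fitted)
  class(out) <- "trend_fit"
  out
}

#' @export
print.trend_fit <- function(x, ...) {
  cat("Effect-size trend model [", x$structure, "]: n =", x$n,
      ", smooth edf =", round(x$edf_smooth, 2),
      ", AICc =", round(x$aicc, 2), "\n")
  invisible(x)
}

#' Rank trend-model structures by AICc
#'
#' Fits each candidate structure (from intercept-only to per-taxon smooths)
#' and ranks by AICc computed from the model's effective degrees of freedom.
#'
#' @inheritParams fit_trend_model
#' @param candidates structure names; default [trend_candidates()].
#' @return list with `ranking` data.frame and `best` `trend_fit`.
#' @export
select_trend_model <- function(effects, candidates = trend_candidates(),
                               k = 10, weight_by_variance = FALSE) {
  fits <- lapply(candidates, function(s)
    tryCatch(fit_trend_model(effects, s, k = k,
                             weight_by_variance = weight_by_variance),
             error = function(e) NULL))
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stop("all trend models failed to fit", call. = FALSE)
  fits <- fits[ok]
  ranking <- data.frame(
    model = candidates[ok],
    edf_smooth = vapply(fits, `[[`, numeric(1), "edf_smooth"),
    k_eff = vapply(fits, `[[`, numeric(1), "k_eff"),
    logLik = vapply(fits, `[[`, numeric(1), "logLik"),
    AICc = vapply(fits, `[[`, numeric(1), "aicc"),
    stringsAsFactors = FALSE)
  ord <- order(ranking$AICc, ranking$k_eff)
  ranking <- ranking[ord, ]
  ranking$dAICc <- ranking$AICc - ranking$AICc[1]
  rownames(ranking) <- NULL
  list(ranking = ranking, best = fits[[ord[1]]])
}

#' Divergence between control and stressor performance curves
#'
#' Computes, at each gradient value, the difference between the predicted
#' control-condition curve and the predicted added-stressor curve from the
#' same fitted performance-curve model, optionally paired with the mean
#' interaction effect size observed at that level. The divergence between
#' curves is the quantity the effect size is expected to track linearly.
#'
#' @param fit a `curve_model_fit` containing both conditions.
#' @param stressor_condition the added-stressor condition label.
#' @param x gradient values; defaults to the basis reference levels. Values
#'   outside the fitted range are flagged.
#' @param control_condition baseline condition label (default `"control"`).
#' @param effects optional interaction-effect table; when given, the mean
#'   Hedge's d (additive null) per level for `stressor_condition` is joined
#'   as `effect_size`.
#' @return data.frame with `x`, `control_fit`, `stressor_fit`, `difference`,
#'   `extrapolated` and (when `effects` is given) `effect_size`.
#' @export
curve_divergence <- function(fit, stressor_condition, x = NULL,
                             control_condition = "control", effects = NULL) {
  stopifnot(inherits(fit, "curve_model_fit"))
  for (cond in c(control_condition, stressor_condition))
    if (!cond %in% fit$conditions)
      stop("condition not in fitted model: ", cond, call. = FALSE)
  if (is.null(x)) x <- fit$basis$reference
  pc <- predict(fit, condition = control_condition, x = x)
  ps <- predict(fit, condition = stressor_condition, x = x)
  out <- data.frame(x = x, control_fit = pc$fit, stressor_fit = ps$fit,
                    difference = pc$fit - ps$fit,
                    extrapolated = pc$extrapolated)
  if (!is.null(effects)) {
    eff <- effects[!effects$excluded & is.finite(effects$d) &
                     effects$null_model == "additive" &
                     effects$stress_combo == stressor_condition, ]
    mean_d <- tapply(eff$d, eff$level, mean)
    out$effect_size <- as.numeric(mean_d[as.character(out$x)])
  }
  out
}

#' Regression of interaction effect size on curve divergence
#'
#' Ordinary least squares of the effect size on the control-minus-stressor
#' curve difference, quantifying the proportionality between curve
#' divergence and multistressor effect size.
#'
#' @param records data.frame with columns `difference` and `effect_size`
#'   (e.g. from [curve_divergence()] with `effects` supplied).
#' @return list with `slope`, `intercept`, `r_squared` and the `lm` fit.
#' @export
divergence_effect_regression <- function(records) {
  rec <- records[is.finite(records$difference) & is.finite(records$effect_size), ]
  if (nrow(rec) < 3)
    stop("need at least 3 divergence records", call. = FALSE)
  if (var(rec$difference) == 0)
    stop("zero variance in curve differences; regression undefined",
         call. = FALSE)
  m <- lm(effect_size ~ difference, data = rec)
  list(slope = unname(coef(m)[2]), intercept = unname(coef(m)[1]),
       r_squared = summary(m)$r.squared, model = m)
}
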