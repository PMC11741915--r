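#' Orthogonal polynomial basis over a gradient
#'
#' Builds degree-1 and degree-2 orthonormal polynomial columns over a set of
#' reference gradient values (QR orthogonalization of `[x, x^2]` against the
#' intercept, the construction behind `stats::poly()`). Both columns have zero
#' mean and unit norm on the reference values, the linear column increases
#' with `x`, and the basis can be evaluated at new gradient values. Because
#' linear and quadratic columns are decorrelated, the fitted coefficients
#' separate curve height (intercept), position (linear) and width (quadratic).
#'
#' @param x reference gradient values; at least `degree + 1` distinct values.
#' @param degree polynomial degree (default 2).
#' @return An object of class `ortho_basis` with the reference values, the
#'   construction columns and the centering/scaling constants used for
#'   evaluation at new `x`.
#' @examples
#' b <- build_orthogonal_basis(c(1, 2, 3))
#' evaluate_basis(b, c(1, 2, 3))  # (-1,0,1)/sqrt(2) and (1,-2,1)/sqrt(6)
#' @export
build_orthogonal_basis <- function(x, degree = 2) {
  ux <- sort(unique(as.numeric(x)))
  if (length(ux) < degree + 1)
    stop("need at least ", degree + 1, " distinct gradient values, got ",
         length(ux), call. = FALSE)
  p <- poly(ux, degree = degree)
  structure(list(reference = ux, degree = degree,
                 coefs = attr(p, "coefs"),
                 columns = unclass(p)[, , drop = FALSE]),
            class = "ortho_basis")
}

#' @rdname build_orthogonal_basis
#' @param basis an `ortho_basis`.
#' @param newx gradient values at which to evaluate the basis.
#' @export
evaluate_basis <- function(basis, newx) {
  stopifnot(inherits(basis, "ortho_basis"))
  m <- poly(as.numeric(newx), degree = basis$degree, coefs = basis$coefs)
  m <- unclass(m)[, , drop = FALSE]
  colnames(m) <- paste0("P", seq_len(basis$degree))
  m
}

#' @export
print.ortho_basis <- function(x, ...) {
  cat("Orthogonal polynomial basis, degree", x$degree, "over",
      length(x$reference), "reference values in [",
      min(x$reference), ",", max(x$reference), "]\n")
  invisible(x)
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 logLik + 2k + 2k(k+1)/(n - k - 1)`; returns `Inf` when the
#' correction denominator is not positive.
#'
#' @param loglik maximized log-likelihood.
#' @param k number of estimated parameters.
#' @param n number of observations.
#' @export
aicc <- function(loglik, k, n) {
  if (n - k - 1 <= 0) return(Inf)
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Describe a candidate performance-curve model
#'
#' @param degree 1 (linear) or 2 (quadratic).
#' @param stress how the categorical stress factor enters: `"main"` (main
#'   effect only), `"linear"` (interacts with the linear term) or `"full"`
#'   (interacts with all polynomial terms).
#' @param random taxon-level random structure: `"intercept"`, `"linear"`
#'   (random intercept + linear) , `"full"` (random intercept + linear +
#'   quadratic) or `"none"`.
#' @return An object of class `curve_structure`.
#' @export
curve_structure <- function(degree = 2,
                            stress = c("full", "linear", "main"),
                            random = c("full", "linear", "intercept", "none")) {
  stress <- match.arg(stress)
  random <- match.arg(random)
  if (!degree %in% 1:2) stop("'degree' must be 1 or 2", call. = FALSE)
  structure(list(degree = as.integer(degree), stress = stress, random = random),
            class = "curve_structure")
}

structure_label <- function(s) {
  sprintf("deg%d_stress-%s_re-%s", s$degree, s$stress, s$random)
}

#' The default candidate grid for model selection
#'
#' Crosses {linear, quadratic} fixed curvature, {main, linear, full} stress
#' structures and {intercept, linear, full} taxon random structures: 18
#' descriptors spanning the range from the most complex model (quadratic with
#' stress interactions on all terms and full random coefficients) down to a
#' linear model with the stress factor as a main effect only. For degree-1
#' models `"linear"` and `"full"` stress structures coincide; ties are broken
#' by parameter count.
#'
#' @return list of [curve_structure()] descriptors.
#' @export
curve_candidates <- function() {
  grid <- expand.grid(degree = 1:2, stress = c("main", "linear", "full"),
                      random = c("intercept", "linear", "full"),
                      stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i)
    curve_structure(grid$degree[i], grid$stress[i], grid$random[i]))
}

fixed_formula <- function(s, has_stress) {
  rhs <- if (s$degree == 2) {
    if (!has_stress) "P1 + P2"
    else switch(s$stress,
                main = "stress + P1 + P2",
                linear = "stress * P1 + P2",
                full = "stress * (P1 + P2)")
  } else {
    if (!has_stress) "P1"
    else switch(s$stress,
                main = "stress + P1",
                linear = , full = "stress * P1")
  }
  stats::as.formula(paste("growth_rate ~", rhs))
}

random_term <- function(s) {
  if (s$random == "none") return(NULL)
  switch(s$random,
         intercept = "(1 | taxon)",
         linear = "(1 + P1 | taxon)",
         full = if (s$degree == 2) "(1 + P1 + P2 | taxon)" else "(1 + P1 | taxon)")
}

prepare_curve_data <- function(rates, basis) {
  if ("converged" %in% names(rates)) {
    n_drop <- sum(!rates$converged)
    if (n_drop) message("excluding ", n_drop, " non-converged well(s)")
    rates <- rates[rates$converged, ]
  }
  rates <- rates[is.finite(rates$growth_rate), ]
  lev <- unique(rates$stress_combo)
  lev <- c(intersect("control", lev), setdiff(lev, "control"))
  P <- evaluate_basis(basis, rates$level)
  df <- data.frame(growth_rate = rates$growth_rate,
                   taxon = factor(rates$taxon),
                   stress = factor(rates$stress_combo, levels = lev),
                   level = rates$level,
                   P1 = P[, 1],
                   P2 = if (ncol(P) >= 2) P[, 2] else 0)
  df
}

#' Fit the quadratic mixed-effects performance-curve model
#'
#' Fits growth rate against an orthogonal polynomial basis of the gradient,
#' with a categorical `stress` factor (the stressor-combination label)
#' entering as the structure specifies, and taxon-level random deviations of
#' the curve coefficients. The model is the hierarchical quadratic
#' \deqn{r_{xi} = (\beta_0 + \epsilon_{0i}) + (\beta_1 + \epsilon_{1i}) x +
#'       (\beta_2 + \epsilon_{2i}) x^2}
#' with `x` on the orthogonal basis scale, fitted by maximum likelihood via
#' [lme4::lmer()] so that AICc ranking across fixed structures is valid. A
#' singular random-effects fit is retried with a simplified random structure
#' and flagged. With a single taxon (no hierarchy) the fixed-effects model is
#' fitted by `lm()` and flagged singular.
#'
#' @param rates growth-rate table (`taxon`, `stress_combo`, `level`,
#'   `growth_rate`; rows with `converged == FALSE` are dropped).
#' @param structure a [curve_structure()].
#' @param basis optional [build_orthogonal_basis()]; defaults to a degree-2
#'   basis over the union of observed gradient levels so that coefficients
#'   are comparable across stress conditions.
#' @return An object of class `curve_model_fit`: the underlying model plus
#'   the basis, composed per-condition coefficients (`coefficients()`),
#'   per-taxon random deviations, `logLik`, `k`, `n` and `aicc`.
#' @export
fit_curve_model <- function(rates, structure = curve_structure(),
                            basis = NULL) {
  if (is.null(basis)) basis <- build_orthogonal_basis(rates$level, degree = 2)
  df <- prepare_curve_data(rates, basis)
  if (length(unique(df$level)) < 3)
    stop("rates must span at least 3 gradient levels", call. = FALSE)
  tl <- table(unique(df[c("taxon", "level")])$taxon)
  if (any(tl < 2))
    stop("every taxon must appear in at least 2 gradient levels", call. = FALSE)
  has_stress <- nlevels(df$stress) >= 2

  ff <- fixed_formula(structure, has_stress)
  singular <- FALSE
  random_used <- structure$random
  model <- NULL

  if (structure$random != "none" && nlevels(droplevels(df$taxon)) >= 2) {
    order <- c("full", "linear", "intercept")
    try_seq <- order[match(structure$random, order):length(order)]
    for (r in try_seq) {
      s_try <- curve_structure(structure$degree, structure$stress, r)
      full_formula <- stats::as.formula(
        paste(deparse(ff), "+", random_term(s_try)))
      m <- tryCatch(
        suppressMessages(lme4::lmer(full_formula, data = df, REML = FALSE,
                                    control = lme4::lmerControl(calc.derivs = FALSE))),
        error = function(e) NULL)
      if (is.null(m)) next
      random_used <- r
      model <- m
      if (!lme4::isSingular(m, tol = 1e-4)) break
      singular <- TRUE
    }
    if (is.null(model))
      stop("mixed-model fit failed to converge for structure ",
           structure_label(structure), call. = FALSE)
  }
  if (is.null(model)) {
    # no usable hierarchy: fixed effects only
    if (structure$random != "none") singular <- TRUE
    random_used <- "none"
    model <- lm(ff, data = df)
  }

  ll <- logLik(model)
  k <- attr(ll, "df")
  n <- nrow(df)
  fit <- list(model = model, basis = basis, structure = structure,
              random_used = random_used, singular = singular,
              fixed_formula = ff, data = df,
              conditions = levels(df$stress), has_stress = has_stress,
              logLik = as.numeric(ll), k = k, n_obs = n,
              n_fixed = length(fixef_vec(model)),
              aicc = aicc(as.numeric(ll), k, n))
  class(fit) <- "curve_model_fit"
  fit
}

fixef_vec <- function(model) {
  if (inherits(model, "merMod")) lme4::fixef(model) else coef(model)
}

fixef_vcov <- function(model) {
  as.matrix(vcov(model))
}

#' @export
print.curve_model_fit <- function(x, ...) {
  s <- x$structure
  cat("Performance-curve model [", structure_label(s), "]\n", sep = "")
  cat("  n =", x$n_obs, "; k =", x$k, "; logLik =", round(x$logLik, 2),
      "; AICc =", round(x$aicc, 2), "\n")
  if (x$singular)
    cat("  note: singular random-effects fit (random structure used: ",
        x$random_used, ")\n", sep = "")
  print(coef(x), digits = 4)
  invisible(x)
}

# model-matrix row(s) for given condition and basis values
design_rows <- function(fit, condition, P1, P2) {
  nd <- data.frame(P1 = P1, P2 = P2)
  if (fit$has_stress) {
    if (!condition %in% fit$conditions)
      stop("unknown condition: ", condition, call. = FALSE)
    nd$stress <- factor(condition, levels = fit$conditions)
  }
  tt <- stats::delete.response(stats::terms(fit$fixed_formula))
  model.matrix(tt, nd)
}

#' Composed per-condition curve coefficients
#'
#' Returns, for every stress condition, the intercept (height), linear
#' (position) and quadratic (width) coefficient on the orthogonal-basis
#' scale, composed from the fixed effects.
#'
#' @param object a `curve_model_fit`.
#' @param ... unused.
#' @export
coef.curve_model_fit <- function(object, ...) {
  beta <- fixef_vec(object$model)
  conds <- if (object$has_stress) object$conditions else "all"
  out <- t(vapply(conds, function(cond) {
    X <- design_rows(object, cond, P1 = c(0, 1, 0), P2 = c(0, 0, 1))
    v <- drop(X %*% beta)
    c(intercept = v[1], linear = v[2] - v[1], quadratic = v[3] - v[1])
  }, numeric(3)))
  as.data.frame(out)
}

#' Per-taxon random deviations of the curve coefficients
#'
#' @param fit a `curve_model_fit`.
#' @return matrix (taxa x 3) of deviations (eps0, eps1, eps2); zero columns
#'   for terms not in the random structure.
#' @export
taxon_deviations <- function(fit) {
  stopifnot(inherits(fit, "curve_model_fit"))
  taxa <- levels(fit$data$taxon)
  out <- matrix(0, length(taxa), 3,
                dimnames = list(taxa, c("eps0", "eps1", "eps2")))
  if (inherits(fit$model, "merMod")) {
    re <- lme4::ranef(fit$model)$taxon
    if ("(Intercept)" %in% names(re)) out[rownames(re), "eps0"] <- re[["(Intercept)"]]
    if ("P1" %in% names(re)) out[rownames(re), "eps1"] <- re[["P1"]]
    if ("P2" %in% names(re)) out[rownames(re), "eps2"] <- re[["P2"]]
  }
  out
}

#' Fit and rank candidate curve models by AICc
#'
#' Fits every candidate structure by maximum likelihood and ranks by AICc
#' (ties broken by fewer parameters), mirroring the strategy of fitting all
#' structures from the most complex quadratic interaction model down to the
#' simplest linear main-effects model and keeping the AICc minimizer.
#'
#' @param rates growth-rate table.
#' @param candidates list of [curve_structure()]; default [curve_candidates()].
#' @param basis optional shared basis.
#' @return list with `ranking` (data.frame: model, degree, stress, random, k,
#'   logLik, AICc, dAICc, singular) and `best` (the winning `curve_model_fit`).
#' @export
select_model <- function(rates, candidates = curve_candidates(), basis = NULL) {
  if (length(candidates) < 2)
    stop("need at least 2 candidate structures", call. = FALSE)
  if (is.null(basis)) basis <- build_orthogonal_basis(rates$level, degree = 2)
  fits <- lapply(candidates, function(s)
    tryCatch(fit_curve_model(rates, s, basis = basis), error = function(e) NULL))
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stop("all candidate models failed to fit", call. = FALSE)
  fits <- fits[ok]
  candidates <- candidates[ok]
  ranking <- data.frame(
    model = vapply(candidates, structure_label, character(1)),
    degree = vapply(candidates, `[[`, integer(1), "degree"),
    stress = vapply(candidates, `[[`, character(1), "stress"),
    random = vapply(candidates, `[[`, character(1), "random"),
    k = vapply(fits, `[[`, numeric(1), "k"),
    logLik = vapply(fits, `[[`, numeric(1), "logLik"),
    AICc = vapply(fits, `[[`, numeric(1), "aicc"),
    singular = vapply(fits, `[[`, logical(1), "singular"),
    stringsAsFactors = FALSE)
  ord <- order(ranking$AICc, ranking$k)
  ranking <- ranking[ord, ]
  ranking$dAICc <- ranking$AICc - ranking$AICc[1]
  rownames(ranking) <- NULL
  list(ranking = ranking, best = fits[[ord[1]]])
}

coef_design_delta <- function(coefficient) {
  # basis values isolating each composed coefficient as X(hi) - X(lo)
  switch(coefficient,
         intercept = list(lo = c(P1 = 0, P2 = 0), hi = NULL),
         linear = list(lo = c(P1 = 0, P2 = 0), hi = c(P1 = 1, P2 = 0)),
         quadratic = list(lo = c(P1 = 0, P2 = 0), hi = c(P1 = 0, P2 = 1)),
         stop("unknown coefficient: ", coefficient, call. = FALSE))
}

coef_L <- function(fit, condition, coefficient) {
  d <- coef_design_delta(coefficient)
  lo <- design_rows(fit, condition, P1 = d$lo["P1"], P2 = d$lo["P2"])
  if (is.null(d$hi)) return(drop(lo))
  hi <- design_rows(fit, condition, P1 = d$hi["P1"], P2 = d$hi["P2"])
  drop(hi - lo)
}

check_coef_in_model <- function(fit, coefficient) {
  if (coefficient == "quadratic" && fit$structure$degree < 2)
    stop("quadratic coefficient absent from a degree-1 model", call. = FALSE)
  if (!fit$has_stress)
    stop("model contains no stress factor", call. = FALSE)
  varies <- switch(coefficient,
                   intercept = TRUE,
                   linear = fit$structure$stress %in% c("linear", "full"),
                   quadratic = fit$structure$degree == 2 &&
                     fit$structure$stress == "full")
  if (!varies)
    stop("the stress factor does not act on the ", coefficient,
         " coefficient in this model", call. = FALSE)
  invisible(TRUE)
}

#' Contrast one curve coefficient between two stress conditions
#'
#' Estimates the difference `condition_a - condition_b` of a composed curve
#' coefficient (height, position or width on the orthogonal-basis scale) from
#' the fixed-effect covariance, with a t test on residual degrees of freedom
#' (`n_obs - n_fixed`).
#'
#' @param fit a `curve_model_fit` containing the stress factor on that
#'   coefficient.
#' @param coefficient `"intercept"`, `"linear"` or `"quadratic"`.
#' @param condition_a,condition_b stress-condition labels.
#' @return one-row data.frame: estimate, se, t, df, p.
#' @export
curve_contrast <- function(fit, coefficient, condition_a, condition_b) {
  check_coef_in_model(fit, coefficient)
  L <- coef_L(fit, condition_a, coefficient) -
    coef_L(fit, condition_b, coefficient)
  beta <- fixef_vec(fit$model)
  V <- fixef_vcov(fit$model)
  est <- sum(L * beta)
  se <- sqrt(drop(t(L) %*% V %*% L))
  df <- fit$n_obs - fit$n_fixed
  tval <- if (se > 0) est / se else 0
  p <- if (se > 0) 2 * pt(-abs(tval), df) else 1
  data.frame(coefficient = coefficient, condition_a = condition_a,
             condition_b = condition_b, estimate = est, se = se,
             t = tval, df = df, p = p, stringsAsFactors = FALSE)
}

#' All pairwise contrasts of a curve coefficient across stress conditions
#'
#' Computes every condition-pair difference of the chosen coefficient with
#' standard errors from the fixed-effect covariance; raw two-sided p values
#' on residual df and Holm-adjusted p values within the coefficient family.
#'
#' @inheritParams curve_contrast
#' @return data.frame with one row per unordered condition pair: estimate,
#'   se, t, df, p (raw) and p_holm.
#' @export
pairwise_contrasts <- function(fit, coefficient = "intercept") {
  check_coef_in_model(fit, coefficient)
  conds <- fit$conditions
  pairs <- utils::combn(conds, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(i)
    curve_contrast(fit, coefficient, pairs[1, i], pairs[2, i]))
  out <- do.call(rbind, rows)
  out$p_holm <- p.adjust(out$p, method = "holm")
  out
}

#' Predict growth rates from a fitted performance-curve model
#'
#' @param object a `curve_model_fit`.
#' @param condition stress-condition label (ignored if the model has no
#'   stress factor).
#' @param x gradient values; values outside the basis reference range are
#'   flagged as extrapolated.
#' @param level `"population"` (fixed effects only) or `"taxon"` (adds that
#'   taxon's random deviations).
#' @param taxon taxon identifier, required when `level = "taxon"`.
#' @param ... unused.
#' @return data.frame: `x`, `condition`, `fit`, `extrapolated`.
#' @export
predict.curve_model_fit <- function(object, condition = NULL, x,
                                    level = c("population", "taxon"),
                                    taxon = NULL, ...) {
  level <- match.arg(level)
  if (is.null(condition)) condition <- object$conditions[1]
  if (object$has_stress && !condition %in% object$conditions)
    stop("unknown condition: ", condition, call. = FALSE)
  P <- evaluate_basis(object$basis, x)
  P2 <- if (ncol(P) >= 2) P[, 2] else rep(0, length(x))
  X <- design_rows(object, condition, P1 = P[, 1], P2 = P2)
  pred <- drop(X %*% fixef_vec(object$model))
  if (level == "taxon") {
    if (is.null(taxon)) stop("'taxon' required for taxon-level prediction",
                             call. = FALSE)
    dev <- taxon_deviations(object)
    if (!taxon %in% rownames(dev)) stop("unknown taxon: ", taxon, call. = FALSE)
    pred <- pred + dev[taxon, "eps0"] + dev[taxon, "eps1"] * P[, 1] +
      dev[taxon, "eps2"] * P2
  }
  extrap <- x < min(object$basis$reference) | x > max(object$basis$reference)
  if (any(extrap))
    warning("some prediction points lie outside the fitted gradient range",
            call. = FALSE)
  data.frame(x = x, condition = condition, fit = pred, extrapolated = extrap,
             stringsAsFactors = FALSE)
}
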