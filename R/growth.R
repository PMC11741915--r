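#' Gompertz log fold-change growth curve
#'
#' The canonical parameterization used throughout the package, both by the
#' synthetic generator and by [fit_gompertz()]:
#' \deqn{y(t) = A \exp\!\left(-\exp\!\left(\frac{\mu_{max} e}{A}(\lambda - t) + 1\right)\right)}
#' where `y` is the natural-log fold change of biomass, `A` the asymptote
#' (log units), `mu_max` the maximum specific growth rate (per hour) — the
#' slope of the curve at its inflection — and `lambda` the lag time (hours).
#'
#' @param t time in hours.
#' @param mu_max maximum specific growth rate (per hour).
#' @param lag lag time lambda (hours).
#' @param A asymptote in natural-log units of fold change.
#' @return log fold change at `t`.
#' @export
gompertz_log_growth <- function(t, mu_max, lag, A) {
  A * exp(-exp((mu_max * exp(1) / A) * (lag - t) + 1))
}

#' Construct an OD600 time series
#'
#' @param times hours, strictly increasing, `times[1] >= 0`.
#' @param od positive OD600 readings, same length as `times`.
#' @return An object of class `od_timeseries`.
#' @export
od_timeseries <- function(times, od) {
  if (length(times) != length(od))
    stop("'times' and 'od' must have the same length", call. = FALSE)
  if (length(times) && (any(diff(times) <= 0) || times[1] < 0))
    stop("'times' must be strictly increasing and start at >= 0", call. = FALSE)
  if (any(!is.finite(od)) || any(od <= 0))
    stop("all OD readings must be positive and finite", call. = FALSE)
  structure(list(times = as.numeric(times), od = as.numeric(od)),
            class = "od_timeseries")
}

#' @export
print.od_timeseries <- function(x, ...) {
  cat("OD600 time series:", length(x$times), "readings over",
      max(x$times), "h; OD", signif(min(x$od), 3), "-", signif(max(x$od), 3), "\n")
  invisible(x)
}

#' Fit the Gompertz growth model to an OD600 time series
#'
#' Fits the modified Gompertz curve (see [gompertz_log_growth()]) to the log
#' fold change `y(t) = ln(od(t)/od(0))` by bounded nonlinear least squares
#' (Levenberg-Marquardt). Because the observed fold change is measured
#' relative to the first reading, the model is evaluated as the difference
#' of the Gompertz curve at `t` and at the first time point, which makes
#' fitting the exact inverse of simulation. The optimizer uses a 3 x 3
#' multi-start grid: lag at 0, 25% and
#' 50% of the observed time span, and mu_max at 0.5x, 1x and 2x the steepest
#' finite-difference slope of `y`; the asymptote starts at `max(y)`. The best
#' fit by residual sum of squares is returned.
#'
#' Series whose maximum log fold change is below `no_growth_threshold` are
#' declared `no_growth` (mu_max = 0) rather than fitted: flat series carry no
#' information about lag or asymptote and produce unstable fits.
#'
#' @param series an [od_timeseries()] (or list with `times` and `od`).
#' @param no_growth_threshold log fold-change below which a well is treated
#'   as non-growing (default 0.05).
#' @return An object of class `gompertz_fit` with elements `mu_max`, `lag`,
#'   `asymptote`, `rss`, `converged`, `no_growth`, `n`.
#' @examples
#' ts <- generate_od_timeseries(rate = 0.5, lag = 2, asymptote = 3, od_sd = 0)
#' fit_gompertz(ts)
#' @export
fit_gompertz <- function(series, no_growth_threshold = 0.05) {
  if (!inherits(series, "od_timeseries"))
    series <- od_timeseries(series$times, series$od)
  t <- series$times
  y <- log(series$od / series$od[1])
  n <- length(t)
  if (n < 4L)
    stop("at least 4 observations are required to fit the Gompertz model",
         call. = FALSE)

  if (max(y) < no_growth_threshold) {
    return(structure(list(mu_max = 0, lag = 0, asymptote = max(0, max(y)),
                          rss = sum((y - mean(y))^2), converged = TRUE,
                          no_growth = TRUE, n = n),
                     class = "gompertz_fit"))
  }

  span <- max(t) - min(t)
  slope <- max(diff(y) / diff(t))
  slope <- if (is.finite(slope) && slope > 0) slope else max(y) / span
  a0 <- max(y)
  dat <- data.frame(t = t, y = y)
  starts <- expand.grid(lag = min(t) + span * c(0, 0.25, 0.5),
                        mu = slope * c(0.5, 1, 2))

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ gompertz_log_growth(t, mu, lag, A) -
          gompertz_log_growth(min(t), mu, lag, A),
        data = dat,
        start = list(A = a0, mu = starts$mu[i], lag = starts$lag[i]),
        lower = c(A = 1e-8, mu = 0, lag = 0),
        upper = c(A = Inf, mu = Inf, lag = max(t)),
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                             ptol = 1e-15)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(resid(fit)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(coef = coef(fit), rss = rss)
  }

  if (is.null(best)) {
    return(structure(list(mu_max = NA_real_, lag = NA_real_,
                          asymptote = NA_real_, rss = NA_real_,
                          converged = FALSE, no_growth = FALSE, n = n),
                     class = "gompertz_fit"))
  }
  structure(list(mu_max = unname(best$coef["mu"]),
                 lag = unname(best$coef["lag"]),
                 asymptote = unname(best$coef["A"]),
                 rss = best$rss, converged = TRUE, no_growth = FALSE, n = n),
            class = "gompertz_fit")
}

#' @export
print.gompertz_fit <- function(x, ...) {
  if (x$no_growth) {
    cat("Gompertz fit: no growth (mu_max = 0)\n")
  } else if (!x$converged) {
    cat("Gompertz fit: did not converge\n")
  } else {
    cat(sprintf("Gompertz fit: mu_max = %.4f /h, lag = %.2f h, A = %.3f (RSS %.3g, n = %d)\n",
                x$mu_max, x$lag, x$asymptote, x$rss, x$n))
  }
  invisible(x)
}

well_key <- function(df) {
  paste(df$taxon, df$stress_combo, df$level, df$replicate, sep = "\r")
}

#' Extract growth rates from a plate of OD600 time series
#'
#' Splits a long-format OD table into per-well series, fits each with
#' [fit_gompertz()], and returns one growth-rate record per well. Non-growing
#' wells get `growth_rate = 0`; wells where the optimizer fails from every
#' start are flagged `converged = FALSE` with `growth_rate = NA` and should be
#' excluded from downstream fits (a message reports their count).
#'
#' @param od_table data.frame with columns `taxon`, `gradient`,
#'   `stress_combo`, `level`, `replicate`, `time_h`, `od600`.
#' @param no_growth_threshold passed to [fit_gompertz()].
#' @return data.frame with one row per well: `taxon`, `gradient`,
#'   `stress_combo`, `level`, `replicate`, `growth_rate`, `no_growth`,
#'   `converged`, `rss`.
#' @export
rates_from_plate <- function(od_table, no_growth_threshold = 0.05) {
  required <- c("taxon", "gradient", "stress_combo", "level", "replicate",
                "time_h", "od600")
  missing_cols <- setdiff(required, names(od_table))
  if (length(missing_cols))
    stop("od table is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  bad <- which(!complete.cases(od_table[required]) |
                 !is.finite(od_table$od600) | od_table$od600 <= 0)
  if (length(bad))
    stop("unparseable OD rows (missing or non-positive values) at lines: ",
         paste(head(bad, 10), collapse = ", "),
         if (length(bad) > 10) " ...", call. = FALSE)
  dup <- duplicated(od_table[c("taxon", "stress_combo", "level", "replicate",
                               "time_h")])
  if (any(dup))
    stop("duplicate (taxon, stress_combo, level, replicate, time) rows at lines: ",
         paste(head(which(dup), 10), collapse = ", "), call. = FALSE)

  wells <- split(od_table, well_key(od_table))
  records <- lapply(wells, function(w) {
    w <- w[order(w$time_h), ]
    fit <- fit_gompertz(od_timeseries(w$time_h, w$od600),
                        no_growth_threshold = no_growth_threshold)
    data.frame(taxon = w$taxon[1], gradient = w$gradient[1],
               stress_combo = w$stress_combo[1], level = w$level[1],
               replicate = w$replicate[1],
               growth_rate = if (fit$converged) fit$mu_max else NA_real_,
               no_growth = fit$no_growth, converged = fit$converged,
               rss = fit$rss, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, records)
  rownames(out) <- NULL
  out <- out[order(out$taxon, out$stress_combo, out$level, out$replicate), ]
  n_fail <- sum(!out$converged)
  if (n_fail)
    message(n_fail, " well(s) failed to converge and are flagged for exclusion")
  rownames(out) <- NULL
  out
}
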