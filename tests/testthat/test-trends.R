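test_that("a constant effect size yields a fully shrunk smooth", {
  eff <- effects_from_fun(function(x, i) 0.4, noise_sd = 0)
  fit <- fit_trend_model(eff, "global")
  expect_lt(fit$edf_smooth, 0.5)
  expect_true(all(abs(fit$fitted$fit - 0.4) < 1e-6))
})

test_that("a noiseless smooth trend is captured to high accuracy", {
  eff <- effects_from_fun(function(x, i) 0.002 * (x - 30)^2 - 0.5,
                          noise_sd = 0)
  fit <- fit_trend_model(eff, "global")
  truth <- 0.002 * (eff$level - 30)^2 - 0.5
  expect_lt(max(abs(fit$fitted$fit - truth)), 1e-3)
})

test_that("per-taxon smooths recover opposite linear trends", {
  eff <- effects_from_fun(function(x, i) (if (i == 1) 0.05 else -0.05) * (x - 30),
                          taxa = c("t01", "t02"), noise_sd = 0.02, seed = 4)
  fit <- fit_trend_model(eff, "by_taxon")
  f <- fit$fitted
  slope <- function(tx) {
    s <- f[f$taxon == tx, ]
    coef(lm(fit ~ level, s))[2]
  }
  expect_gt(slope("t01"), 0.03)
  expect_lt(slope("t02"), -0.03)
})

test_that("trend structure selection responds to taxon heterogeneity", {
  # shared trend: the global-smooth model is competitive with the best
  shared <- effects_from_fun(function(x, i) 0.05 * (x - 30),
                             noise_sd = 0.3, seed = 7)
  sel_shared <- select_trend_model(shared)
  r <- sel_shared$ranking
  expect_lte(r$AICc[r$model == "global"] - min(r$AICc), 2)
  # distinct trends: the per-taxon model wins
  distinct <- effects_from_fun(
    function(x, i) (if (i %% 2) 0.08 else -0.08) * (x - 30),
    noise_sd = 0.3, seed = 8)
  sel_distinct <- select_trend_model(distinct)
  expect_equal(sel_distinct$ranking$model[1], "by_taxon")
  # pure noise at the study's taxon count: the gradient smooth is shrunk away
  noise <- effects_from_fun(function(x, i) 0, taxa = sprintf("t%02d", 1:12),
                            noise_sd = 1, seed = 9)
  fit_noise <- fit_trend_model(noise, "global")
  expect_lt(fit_noise$edf_smooth, 0.5)
  r2 <- select_trend_model(noise)$ranking
  expect_lte(r2$AICc[r2$model == "intercept"] - min(r2$AICc), 2)
})

test_that("smooth structures demand enough levels per taxon", {
  eff <- effects_from_fun(function(x, i) 0.1 * x, levels = c(10, 20, 30))
  expect_error(fit_trend_model(eff, "global"), "5 distinct")
})

test_that("an exactly linear trend is fitted as a line", {
  eff <- effects_from_fun(function(x, i) 0.04 * (x - 30) + 0.2, noise_sd = 0)
  fit <- fit_trend_model(eff, "global")
  lin <- lm(d ~ level, data.frame(d = eff$d, level = eff$level))
  expect_lt(max(abs(fit$fitted$fit - fitted(lin))), 0.02)
})

test_that("AICc ranking of trend models ignores a constant shift in d", {
  eff <- effects_from_fun(function(x, i) 0.05 * (x - 30), noise_sd = 0.3,
                          seed = 12)
  r1 <- select_trend_model(eff)$ranking
  eff2 <- eff
  eff2$d <- eff2$d + 5
  r2 <- select_trend_model(eff2)$ranking
  m <- match(r1$model, r2$model)
  expect_equal(r2$AICc[m] - min(r2$AICc), r1$AICc - min(r1$AICc),
               tolerance = 1e-3)
})

test_that("curve divergence is zero between identical conditions", {
  tab <- generate_rate_table(wide_spec(), small_design(n_taxa = 3),
                             noise_spec(rate_sd = 0.02, seed = 5))
  fit <- fit_curve_model(tab, curve_structure(2, "full", "intercept"))
  div <- curve_divergence(fit, stressor_condition = "control")
  expect_true(all(abs(div$difference) < 1e-12))
})

test_that("a constant height offset appears as a constant divergence", {
  lv <- c(15, 20, 24, 28, 32, 36)
  f <- function(x) 1.2 * (1 - ((x - 27) / 30)^2)
  groups <- list()
  for (tx in c("t1", "t2")) for (s in lv) {
    groups <- c(groups, list(
      list(taxon = tx, combo = "control", level = s, values = rep(f(s), 3)),
      list(taxon = tx, combo = "B", level = s, values = rep(f(s) - 0.3, 3))))
  }
  tab <- rate_table_from_groups(groups)
  fit <- fit_curve_model(tab, curve_structure(2, "full", "intercept"))
  div <- curve_divergence(fit, stressor_condition = "B")
  expect_equal(div$difference, rep(0.3, nrow(div)), tolerance = 1e-6)
})

test_that("divergence-effect regression is exact on collinear records", {
  rec <- data.frame(difference = c(0.1, 0.2, 0.3, 0.4),
                    effect_size = 2 * c(0.1, 0.2, 0.3, 0.4) - 0.1)
  reg <- suppressWarnings(divergence_effect_regression(rec))
  expect_equal(reg$slope, 2, tolerance = 1e-12)
  expect_equal(reg$r_squared, 1, tolerance = 1e-12)
  degenerate <- data.frame(difference = c(0, 0, 0), effect_size = c(0, 0, 0))
  expect_error(divergence_effect_regression(degenerate), "zero variance")
})
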