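test_that("additive predictions follow the null model with zero clamping", {
  expect_equal(additive_prediction(G_Ac = 1.0, G_As = 0.6, G_Bc = 0.7), 0.3)
  expect_equal(additive_prediction(G_Ac = 1.0, G_As = 0.1, G_Bc = 0.2), 0)
  expect_equal(additive_prediction(1.0, 0.6, 0.7, G_Cc = 0.8), 0.1)
  expect_error(additive_prediction(G_Ac = 1, G_As = 0.5, G_Bc = NULL),
               "requires")
})

test_that("multiplicative predictions multiply relative effects", {
  expect_equal(multiplicative_prediction(1.0, 0.5, 0.8), 0.4)
  expect_equal(multiplicative_prediction(0.8, 0.8, 0.8), 0.8)  # identity
  expect_error(multiplicative_prediction(0, 0.5, 0.8), "zero")
})

test_that("the null models coincide when the added stressor has no effect", {
  for (i in 1:20) {
    set.seed(i)
    Ac <- runif(1, 0.2, 1.5)
    As <- runif(1, 0, 1.5)
    expect_equal(additive_prediction(Ac, As, Ac),
                 multiplicative_prediction(Ac, As, Ac), tolerance = 1e-12)
  }
})

test_that("Hedge's d matches the hand-worked example", {
  obs <- group_stats(c(0.30, 0.35, 0.40))
  pred <- group_stats(c(0.50, 0.55, 0.60))
  h <- hedges_d(obs, pred)
  expect_equal(h$s_pooled, 0.05)
  expect_equal(h$J, 0.8)
  expect_equal(h$d, 3.2)
  expect_equal(h$var_d, 6 / 9 + 3.2^2 / 12)
  expect_equal(classify_interaction(h$d, h$ci), "synergistic")
})

test_that("equal groups give d = 0 with a symmetric CI; constants error", {
  g <- group_stats(c(0.4, 0.5, 0.6))
  h <- hedges_d(g, g)
  expect_equal(h$d, 0)
  expect_equal(h$ci[1], -h$ci[2])
  flat <- group_stats(c(0.5, 0.5, 0.5))
  expect_error(hedges_d(flat, flat), "pooled standard deviation")
})

test_that("classification follows the CI rule", {
  expect_equal(classify_interaction(0.5, c(0.1, 0.9)), "synergistic")
  expect_equal(classify_interaction(-0.5, c(-0.9, -0.1)), "antagonistic")
  expect_equal(classify_interaction(0.3, c(-0.1, 0.7)), "additive")
})

test_that("effects are computed for every taxon at every non-control level", {
  tab <- generate_rate_table(default_curve_spec(), default_plate_design(),
                             noise_spec(seed = 21))
  sc <- stressor_scenario("pH", "pH", control_level = 20)
  eff <- suppressMessages(
    interactions_along_gradient(tab, sc,
                                null_models = c("additive", "multiplicative")))
  expect_equal(sum(eff$null_model == "additive"), 12 * 8)
  expect_equal(sum(eff$null_model == "multiplicative"), 12 * 8)
  expect_false(20 %in% eff$level)  # control level excluded
  # three-way scenario adds the G_Cc term
  sc3 <- stressor_scenario("pH x salinity", c("pH", "salinity"),
                           control_level = 20)
  eff3 <- suppressMessages(
    interactions_along_gradient(tab, sc3, null_models = "additive"))
  expect_equal(nrow(eff3), 12 * 8)
})

test_that("data constructed to match the additive null classify as additive", {
  lv <- c(10, 20, 30, 40)
  dev <- c(-0.02, 0, 0.02)   # mean-preserving replicate spread
  groups <- list()
  for (s in lv) {
    A_s <- 0.9 - 0.01 * abs(s - 20)   # A_c = 0.9 at the control level
    pred <- A_s + 0.7 - 0.9           # B_c = 0.7 (also the combined value at 20)
    groups <- c(groups, list(
      list(taxon = "t1", combo = "control", level = s, values = A_s + dev),
      list(taxon = "t1", combo = "B", level = s, values = pred + dev)))
  }
  tab <- rate_table_from_groups(groups)
  sc <- stressor_scenario("B", "B", control_level = 20)
  eff <- interactions_along_gradient(tab, sc, null_models = "additive")
  expect_true(all(eff$classification == "additive"))
  expect_true(all(abs(eff$d) < 1e-8))
})

test_that("observations far below the prediction classify as synergistic", {
  lv <- c(10, 20, 30)
  dev <- c(-0.02, 0, 0.02)
  groups <- list()
  for (s in lv) {
    A_s <- 0.9
    pred <- A_s + 0.7 - 0.9
    obs <- pred - 0.4        # many pooled sd below the prediction
    combo_vals <- if (s == 20) 0.7 + dev else obs + dev
    groups <- c(groups, list(
      list(taxon = "t1", combo = "control", level = s, values = A_s + dev),
      list(taxon = "t1", combo = "B", level = s, values = combo_vals)))
  }
  tab <- rate_table_from_groups(groups)
  sc <- stressor_scenario("B", "B", control_level = 20)
  eff <- interactions_along_gradient(tab, sc, null_models = "additive")
  expect_true(all(eff$classification == "synergistic"))
  expect_true(all(eff$d > 0))
})

test_that("classification is invariant to rescaling all growth rates", {
  tab <- generate_rate_table(default_curve_spec(), default_plate_design(),
                             noise_spec(seed = 33))
  sc <- stressor_scenario("salinity", "salinity", control_level = 20)
  eff1 <- suppressMessages(
    interactions_along_gradient(tab, sc, null_models = "additive"))
  tab2 <- tab
  tab2$growth_rate <- tab2$growth_rate * 7.3
  eff2 <- suppressMessages(
    interactions_along_gradient(tab2, sc, null_models = "additive"))
  expect_equal(eff2$d, eff1$d, tolerance = 1e-10)
  expect_identical(eff2$classification, eff1$classification)
})

test_that("zero-growth cells follow the zero-zero-additive rule", {
  # all groups flat: the pooled sd is exactly zero at the extreme level
  groups <- list(
    list(taxon = "t1", combo = "control", level = 20, values = rep(0.9, 3)),
    list(taxon = "t1", combo = "control", level = 40, values = c(0, 0, 0)),
    list(taxon = "t1", combo = "B", level = 20, values = rep(0.1, 3)),
    list(taxon = "t1", combo = "B", level = 40, values = c(0, 0, 0)))
  tab <- rate_table_from_groups(groups)
  sc <- stressor_scenario("B", "B", control_level = 20)
  eff <- interactions_along_gradient(tab, sc, null_models = "additive")
  expect_equal(eff$classification, "additive")
  expect_equal(eff$d, 0)
  eff2 <- interactions_along_gradient(tab, sc, null_models = "additive",
                                      zero_zero_additive = FALSE)
  expect_true(eff2$excluded)
})

test_that("frequencies conserve counts and panel totals", {
  tab <- generate_rate_table(default_curve_spec(), default_plate_design(),
                             noise_spec(seed = 21))
  sc <- stressor_scenario("pH", "pH", control_level = 20)
  eff <- suppressMessages(
    interactions_along_gradient(tab, sc, null_models = "additive"))
  fr <- interaction_frequencies(eff)
  per <- fr[!is.na(fr$level), ]
  tot <- fr[is.na(fr$level), ]
  # per-level counts sum to the number of computable effects at that level
  for (s in unique(per$level)) {
    expect_equal(sum(per$n[per$level == s]),
                 sum(!eff$excluded & eff$level == s))
  }
  # panel totals equal the sum of their per-level counts
  for (cl in unique(tot$classification)) {
    expect_equal(tot$n[tot$classification == cl],
                 sum(per$n[per$classification == cl]))
  }
  # an all-additive table leaves the other rows at zero
  eff_add <- eff
  eff_add$classification <- "additive"
  fr_add <- interaction_frequencies(eff_add)
  expect_equal(sum(fr_add$n[fr_add$classification != "additive"]), 0)
})
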