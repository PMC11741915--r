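test_that("orthogonal basis matches the hand Gram-Schmidt construction", {
  b <- build_orthogonal_basis(c(1, 2, 3))
  M <- evaluate_basis(b, c(1, 2, 3))
  expect_equal(M[, "P1"], c(-1, 0, 1) / sqrt(2), tolerance = 1e-12)
  expect_equal(M[, "P2"], c(1, -2, 1) / sqrt(6), tolerance = 1e-12)
})

test_that("basis columns are orthonormal and orthogonal to the intercept", {
  set.seed(5)
  for (i in 1:5) {
    x <- sort(runif(sample(4:12, 1), 0, 50))
    b <- build_orthogonal_basis(x)
    M <- evaluate_basis(b, b$reference)
    expect_lt(abs(sum(M[, 1])), 1e-10)
    expect_lt(abs(sum(M[, 2])), 1e-10)
    expect_lt(abs(sum(M[, 1] * M[, 2])), 1e-10)
    expect_equal(colSums(M^2), c(P1 = 1, P2 = 1), tolerance = 1e-10)
    expect_gt(M[nrow(M), 1], M[1, 1])  # linear column increases with x
  }
})

test_that("degenerate gradients cannot support a quadratic basis", {
  expect_error(build_orthogonal_basis(c(5, 5, 5)), "distinct")
  expect_error(build_orthogonal_basis(c(1, 2)), "distinct")
})

test_that("AICc applies the small-sample correction", {
  # AIC = 100 with k = 3, n = 10: correction 2*3*4/6 = 4
  ll <- -(100 - 2 * 3) / 2
  expect_equal(aicc(ll, 3, 10), 104)
  expect_equal(aicc(ll, 3, 1e9), 100, tolerance = 1e-6)
  expect_identical(aicc(ll, 9, 10), Inf)
})

test_that("noiseless quadratic data are reproduced exactly by the fit", {
  sp <- wide_spec()
  d <- small_design(n_taxa = 3)
  tab <- generate_rate_table(sp, d, noise_spec(rate_sd = 0, seed = 1))
  fit <- fit_curve_model(tab, curve_structure(2, "full", "intercept"))
  for (combo in c("control", "pH")) {
    n_add <- if (combo == "control") 0 else 1
    pr <- predict(fit, condition = combo, x = d$gradient_levels)
    expect_equal(pr$fit, true_rate(sp, d$gradient_levels, n_add),
                 tolerance = 1e-6)
  }
})

test_that("stored AICc matches recomputation and nesting is monotone", {
  tab <- generate_rate_table(default_curve_spec(), default_plate_design(),
                             noise_spec(seed = 8))
  f_main <- fit_curve_model(tab, curve_structure(2, "main", "intercept"))
  f_full <- fit_curve_model(tab, curve_structure(2, "full", "intercept"))
  for (f in list(f_main, f_full))
    expect_equal(f$aicc, aicc(f$logLik, f$k, f$n_obs), tolerance = 1e-10)
  # the main-effect model is nested in the full interaction model
  expect_gte(f_full$logLik, f_main$logLik)
})

test_that("random deviations are centred and average to the population curve", {
  tab <- generate_rate_table(default_curve_spec(), default_plate_design(),
                             noise_spec(seed = 8))
  fit <- fit_curve_model(tab, curve_structure(2, "full", "full"))
  dev <- taxon_deviations(fit)
  expect_equal(colMeans(dev), c(eps0 = 0, eps1 = 0, eps2 = 0),
               tolerance = 0.02)
  x <- fit$basis$reference
  pop <- predict(fit, "control", x)$fit
  per_taxon <- sapply(rownames(dev), function(tx)
    predict(fit, "control", x, level = "taxon", taxon = tx)$fit)
  expect_equal(rowMeans(per_taxon), pop, tolerance = 0.02)
})

test_that("contrasts are antisymmetric and vanish for identical conditions", {
  tab <- generate_rate_table(default_curve_spec(), default_plate_design(),
                             noise_spec(seed = 8))
  fit <- fit_curve_model(tab, curve_structure(2, "full", "intercept"))
  self <- curve_contrast(fit, "intercept", "pH", "pH")
  expect_equal(self$estimate, 0)
  expect_equal(self$p, 1)
  ab <- curve_contrast(fit, "linear", "control", "pH")
  ba <- curve_contrast(fit, "linear", "pH", "control")
  expect_equal(ab$estimate, -ba$estimate)
  expect_equal(ab$p, ba$p)
  pc <- pairwise_contrasts(fit, "intercept")
  expect_equal(nrow(pc), choose(4, 2))
  expect_true(all(pc$p >= 0 & pc$p <= 1))
  expect_true(all(pc$p_holm >= pc$p))
})

test_that("contrasts require the stress factor on the requested coefficient", {
  tab <- generate_rate_table(default_curve_spec(), default_plate_design(),
                             noise_spec(seed = 8))
  f_main <- fit_curve_model(tab, curve_structure(2, "main", "intercept"))
  expect_error(pairwise_contrasts(f_main, "linear"), "does not act")
  f_lin <- fit_curve_model(tab, curve_structure(1, "full", "intercept"))
  expect_error(pairwise_contrasts(f_lin, "quadratic"), "degree-1")
})

test_that("a single-taxon fit degrades to fixed effects with a singular flag", {
  tab <- generate_rate_table(wide_spec(), small_design(n_taxa = 1),
                             noise_spec(rate_sd = 0.02, seed = 2))
  fit <- fit_curve_model(tab, curve_structure(2, "full", "full"))
  expect_true(fit$singular)
  expect_s3_class(coef(fit), "data.frame")
})

test_that("model selection favours curvature when it is real", {
  tab <- generate_rate_table(default_curve_spec(), default_plate_design(),
                             noise_spec(seed = 12))
  sel <- select_model(tab)
  expect_equal(nrow(sel$ranking), 18)
  expect_equal(sel$ranking$dAICc[1], 0)
  expect_equal(sel$ranking$degree[1], 2)
  # every quadratic model with matching structure beats its linear twin
  r <- sel$ranking
  best_quad <- min(r$AICc[r$degree == 2])
  best_lin <- min(r$AICc[r$degree == 1])
  expect_lt(best_quad, best_lin)
})

test_that("fixed-effect RMSE shrinks with more replicates", {
  sp <- wide_spec(taxon_sd = c(0.05, 1, 1))
  rmse <- sapply(c(3, 12), function(reps) {
    tab <- generate_rate_table(sp, small_design(n_taxa = 6, replicates = reps),
                               noise_spec(rate_sd = 0.15, seed = 31))
    fit <- fit_curve_model(tab, curve_structure(2, "full", "intercept"))
    x <- fit$basis$reference
    sqrt(mean((predict(fit, "control", x)$fit - true_rate(sp, x))^2))
  })
  expect_lt(rmse[2], rmse[1])
})
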