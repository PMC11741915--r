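# Small fixtures shared across test files. Everything is generated in code;
# no data files are read.

# a compact design: fewer taxa/levels than the full study layout, but the
# same structure (control + single stressors + combination)
small_design <- function(n_taxa = 4, combos = c("control", "pH"),
                         levels = c(15, 20, 24, 28, 32, 36),
                         replicates = 3) {
  plate_design(taxa = sprintf("t%02d", seq_len(n_taxa)),
               gradient = "temperature", gradient_levels = levels,
               stress_combos = combos, replicates = replicates,
               control_level = 20)
}

# wide curve whose positive region covers all levels of small_design, so no
# clamping complicates exactness checks
wide_spec <- function(...) {
  args <- list(r_max = 1.2, x_opt = 27, w = 30,
               delta_height = -0.2, delta_position = 6, delta_width = 0,
               taxon_sd = c(0, 0, 0))
  args[names(list(...))] <- list(...)
  do.call(true_curve_spec, args)
}

# hand-built rate table from explicit per-group replicate values:
# groups is a list of lists with taxon, combo, level, values
rate_table_from_groups <- function(groups, gradient = "temperature") {
  do.call(rbind, lapply(groups, function(g)
    data.frame(taxon = g$taxon, gradient = gradient,
               stress_combo = g$combo, level = g$level,
               replicate = seq_along(g$values), growth_rate = g$values,
               stringsAsFactors = FALSE)))
}

# effects-like table for trend-model tests, built directly from d values:
# d_fun(level, taxon_index) -> mean d
effects_from_fun <- function(d_fun, taxa = sprintf("t%02d", 1:6),
                             levels = c(15, 24, 28, 32, 36, 40, 44, 47),
                             noise_sd = 0, seed = 1) {
  set.seed(seed)
  grid <- expand.grid(taxon = taxa, level = levels, stringsAsFactors = FALSE)
  d <- mapply(d_fun, grid$level, match(grid$taxon, taxa)) +
    rnorm(nrow(grid), 0, noise_sd)
  data.frame(taxon = grid$taxon, gradient = "temperature",
             stress_combo = "B", level = grid$level, null_model = "additive",
             d = d, var_d = 0.7, excluded = FALSE,
             classification = "additive", stringsAsFactors = FALSE)
}

# independent straight-line implementations of the null models and Hedge's d,
# kept free of any package helper so they can serve as an oracle
oracle_additive <- function(Ac, As, Bc, Cc = NULL) {
  p <- As - Ac + Bc - Ac + Ac
  if (!is.null(Cc)) p <- p + Cc - Ac
  if (p < 0) 0 else p
}

oracle_multiplicative <- function(Ac, As, Bc, Cc = NULL) {
  p <- Ac * (As / Ac) * (Bc / Ac)
  if (!is.null(Cc)) p <- p * (Cc / Ac)
  p
}

oracle_hedges_d <- function(m_obs, sd_obs, n_obs, m_pred, sd_pred, n_pred) {
  sp <- sqrt(((n_obs - 1) * sd_obs^2 + (n_pred - 1) * sd_pred^2) /
               (n_obs + n_pred - 2))
  J <- 1 - 3 / (4 * (n_obs + n_pred - 2) - 1)
  d <- J * (m_pred - m_obs) / sp
  vd <- (n_obs + n_pred) / (n_obs * n_pred) + d^2 / (2 * (n_obs + n_pred))
  list(d = d, var_d = vd, ci = c(d - 1.96 * sqrt(vd), d + 1.96 * sqrt(vd)))
}
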