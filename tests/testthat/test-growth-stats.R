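# time-shift alignment, slopes, rate aggregation, fold changes, ANOVA

long_obs <- function(df) trait_observations(df)

test_that("time shift aligns cold records two days back and drops out-of-range rows", {
  df <- tibble::tibble(
    plant = "p", genotype = "g", treatment = rep(c("control", "cold"),
                                                 each = 9),
    replicate = 1, das = rep(8:16, 2), trait = "area_px", value = 1)
  sh <- suppressMessages(time_shift(df, 2))
  expect_equal(sh$aligned_das[sh$treatment == "cold" & sh$das == 13], 11)
  # cold das 8 and 9 align to 6, 7: before the control range, dropped
  expect_false(any(sh$treatment == "cold" & sh$das %in% c(8, 9)))
  expect_equal(sum(sh$treatment == "cold"), 7)
  expect_message(time_shift(df, 2), "dropped 2")
  # zero shift is the identity
  sh0 <- time_shift(df, 0)
  expect_equal(sh0$aligned_das, sh0$das)
  expect_equal(nrow(sh0), nrow(df))
})

test_that("per-plant slopes match the closed-form OLS oracle", {
  mk <- function(x, y) tibble::tibble(
    plant = "p", genotype = "g", treatment = "control", replicate = 1,
    das = x, aligned_das = x, trait = "area_px", value = y)
  iv <- tibble::tibble(interval = "w", start = 9, end = 13)
  expect_equal(plant_slopes(mk(c(9, 10, 11), c(10, 15, 20)), iv)$slope, 5)
  expect_equal(plant_slopes(mk(9:13, rep(4, 5)), iv)$slope, 0)
  for (seed in 1:10) {
    y <- withr::with_seed(seed, rnorm(5, 3 * (9:13), 2))
    expect_equal(plant_slopes(mk(9:13, y), iv)$slope,
                 oracle_slope(9:13, y), tolerance = 1e-9)
  }
  # a single time point in the window excludes the plant with a message
  expect_message(out <- plant_slopes(mk(13, 5), iv), "excluded")
  expect_equal(nrow(out), 0)
})

test_that("rate aggregation means, standard errors and order invariance", {
  sl <- tibble::tibble(
    plant = c("a", "b", "c"), genotype = "g",
    treatment = c("cold", "cold", "control"), replicate = 1,
    trait = "area_px", interval = "w", n_obs = 3, slope = c(4, 6, 2))
  r <- aggregate_rates(sl)
  cold <- r[r$treatment == "cold", ]
  expect_equal(cold$mean_slope, 5)
  expect_equal(cold$se, 1)          # sd(4,6)/sqrt(2) = sqrt(2)/sqrt(2)
  expect_equal(cold$n_plants, 2L)
  single <- r[r$treatment == "control", ]
  expect_equal(single$mean_slope, 2)
  expect_true(is.na(single$se))
  expect_equal(aggregate_rates(sl[c(3, 1, 2), ]), r)
})

test_that("log2 fold changes clip non-positive rates and are antisymmetric otherwise", {
  mk_rates <- function(cold, control) tibble::tibble(
    genotype = "g", treatment = rep(c("cold", "control"), each = 1),
    trait = "area_px", interval = "w", mean_slope = c(cold, control),
    se = NA, n_plants = 5)
  expect_equal(log2_fold_change(mk_rates(50, 100))$log2fc, -1)
  expect_equal(log2_fold_change(mk_rates(80, 80))$log2fc, 0)
  clipped <- log2_fold_change(mk_rates(-3, 100), epsilon = 0.01)
  expect_equal(clipped$log2fc, log2(0.01 / 100), tolerance = 1e-9)
  expect_true(clipped$clipped)
  expect_false(log2_fold_change(mk_rates(50, 100))$clipped)
  expect_error(log2_fold_change(mk_rates(1, 2), epsilon = 0),
               class = "coldpheno_invalid_parameter")
  # antisymmetry when nothing is clipped
  for (pair in list(c(20, 90), c(5, 1), c(0.3, 0.7))) {
    a <- log2_fold_change(mk_rates(pair[1], pair[2]))$log2fc
    b <- log2_fold_change(mk_rates(pair[2], pair[1]))$log2fc
    expect_equal(a, -b)
  }
})

test_that("noiseless trajectories recover the exact piecewise slopes", {
  d <- tiny_design(2, seed = 31)
  tab <- simulate_experiment(d, noise = FALSE)
  long <- suppressMessages(time_shift(long_obs(tab)))
  rates <- aggregate_rates(suppressMessages(plant_slopes(long)))
  base <- trait_baselines()
  for (i in 1:2) {
    g <- d$genotypes[i, ]
    for (tr in c("area_px", "height_px")) {
      rate <- base$rate[base$trait == tr] * g$growth_scale
      mult <- if (tr == "height_px") g$height_recovery_multiplier
              else g$recovery_multiplier
      pick <- function(treat, iv) {
        rates$mean_slope[rates$genotype == g$genotype &
                           rates$treatment == treat &
                           rates$trait == tr & rates$interval == iv]
      }
      expect_equal(pick("control", "early_recovery"), rate)
      expect_equal(pick("control", "late_recovery"), rate)
      # cold slopes on the shifted axis are the recovery-phase rates
      expect_equal(pick("cold", "early_recovery"), rate * mult)
      expect_equal(pick("cold", "late_recovery"), rate * mult)
    }
  }
  # cold plants gain exactly nothing during the stress window
  cold <- tab[tab$treatment == "cold", ]
  for (p in unique(cold$plant)[1:3]) {
    sub <- cold[cold$plant == p, ]
    expect_equal(sub$area_px[sub$das == 11], sub$area_px[sub$das == 9])
  }
})

test_that("noisy slope recovery is unbiased", {
  gt <- genotype_panel(1, seed = 2)
  d <- experiment_design(gt, replicates = 1, plots_per_treatment = 67,
                         plants_per_plot = 1, noise_frac = 0.1,
                         plant_scale_sd = 0, seed = 5)
  tab <- simulate_experiment(d)            # 134 plants, both treatments
  ctrl <- tab[tab$treatment == "control", ]
  long <- suppressMessages(time_shift(long_obs(ctrl)))
  sl <- suppressMessages(plant_slopes(long, tibble::tibble(
    interval = "full", start = 8, end = 16)))
  sl <- sl[sl$trait == "area_px", ]
  true_rate <- 100 * gt$growth_scale
  se <- sd(sl$slope) / sqrt(nrow(sl))
  expect_lt(abs(mean(sl$slope) - true_rate), 2 * se + 1e-9)
})

test_that("necrosis ANOVA + Tukey flags only real increases", {
  # identical groups: never significant
  same <- tibble::tibble(das = 13, trait = "percent_necrosis",
                         genotype = "g",
                         treatment = rep(c("control", "cold"), each = 5),
                         value = 5.0)
  r <- necrosis_test(same)
  expect_false(r$significant)
  # strong separation at n = 18/group: flagged
  df <- withr::with_seed(7, tibble::tibble(
    das = 13, trait = "percent_necrosis", genotype = "A",
    treatment = rep(c("control", "cold"), each = 18),
    value = c(rnorm(18, 5, 3), rnorm(18, 30, 5))))
  expect_true(necrosis_test(df)$significant)
  # a *decrease* of the same size is not called significant
  dec <- df
  dec$value <- rev(dec$value)
  dec$treatment <- df$treatment
  expect_false(necrosis_test(dec)$significant)
  # two groups: Tukey-adjusted p equals the plain ANOVA p
  fit <- aov(value ~ treatment, data = df)
  expect_equal(necrosis_test(df)$p_adj,
               summary(fit)[[1]][["Pr(>F)"]][1], tolerance = 1e-9)
  # undersized groups are skipped with a warning
  small <- df[c(1, 19, 20), ]
  expect_warning(out <- necrosis_test(small), "skipped")
  expect_equal(nrow(out), 0)
})

test_that("null necrosis false positives stay within binomial bounds", {
  null_df <- withr::with_seed(19, purrr::map_dfr(1:40, function(i) {
    tibble::tibble(das = 13, trait = "percent_necrosis",
                   genotype = sprintf("G%02d", i),
                   treatment = rep(c("control", "cold"), each = 18),
                   value = rnorm(36, 5, 2))
  }))
  res <- necrosis_test(null_df, alpha = 0.05)
  expect_equal(nrow(res), 40)
  # one-sided alpha/2 per genotype: Bin(40, 0.025), P(X > 4) < 0.003
  expect_lte(sum(res$significant), 4)
})

test_that("fold-change correlation matrices are symmetric with unit diagonal", {
  mk_folds <- function(m, traits, genos) {
    tidyr::expand_grid(genotype = genos, trait = traits, interval = "w") |>
      dplyr::mutate(log2fc = as.vector(t(m)), clipped = FALSE)
  }
  set.seed(3)
  m <- matrix(rnorm(200), 40, 5)
  folds <- mk_folds(m, paste0("t", 1:5), sprintf("G%02d", 1:40))
  cc <- trait_interval_correlation(folds)
  expect_equal(cc, t(cc))
  expect_equal(unname(diag(cc)), rep(1, 5))
  # independent features stay below the null bound
  off <- cc; diag(off) <- 0
  expect_lt(max(abs(off)), 0.45)
  # duplicated feature rows correlate exactly
  dup <- dplyr::bind_rows(folds,
                          dplyr::mutate(folds[folds$trait == "t1", ],
                                        trait = "t9"))
  cc2 <- trait_interval_correlation(dup)
  expect_equal(cc2["t1.w", "t9.w"], 1)
  expect_error(trait_interval_correlation(folds[folds$genotype %in%
                                                  c("G01", "G02"), ]))
})
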