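test_that("strain mean squares reduce to textbook one-way ANOVA", {
  set.seed(1)
  meta <- data.frame(sample_id = sprintf("S%02d", 1:12),
                     strain = rep(c("A", "B", "C"), each = 4),
                     diet = "HP", week = "W1", stringsAsFactors = FALSE)
  y <- rnorm(12, rep(c(5, 7, 6), each = 4))
  ms <- strain_mean_squares(y, meta, covariates = character(0))
  # hand one-way ANOVA arithmetic
  gm <- mean(y)
  sm <- tapply(y, meta$strain, mean)
  ssb <- sum(4 * (sm - gm)^2)
  ssw <- sum((y - sm[meta$strain])^2)
  expect_equal(ms$msb, ssb / 2, tolerance = 1e-12)
  expect_equal(ms$msw, ssw / 9, tolerance = 1e-12)
  # balanced n0 collapses to the replicate count: (12 - 48/12)/2 = 4
  expect_equal(ms$n0, 4)

  # equal strain means with zero noise: MSB = 0
  y0 <- rep(5, 12)
  ms0 <- suppressWarnings(strain_mean_squares(y0, meta,
                                              covariates = character(0)))
  expect_equal(ms0$msb, 0, tolerance = 1e-20)
})

test_that("intraclass correlation and g2 follow their closed forms", {
  expect_equal(intraclass_r(3, 3, 2), 0)
  expect_equal(intraclass_r(3, 1, 2), 0.5)
  expect_equal(genetic_determination_g2(3, 3, 2), 0)
  expect_equal(genetic_determination_g2(3, 1, 2), 1 / 3)
  # MSB < MSW gives legal negative heritability
  expect_lt(intraclass_r(1, 2, 3), 0)
  # zero within-strain mean square saturates at 1 with a flag
  r1 <- intraclass_r(3, 0, 2)
  expect_equal(as.numeric(r1), 1)
  expect_identical(attr(r1, "flag"), "MSW zero")
  expect_equal(as.numeric(genetic_determination_g2(3, 1e-12, 2)), 1,
               tolerance = 1e-9)
  # g2 < r_I whenever MSB > MSW (strict, n0 > 1)
  set.seed(2)
  for (i in 1:50) {
    msw <- runif(1, 0.1, 1); msb <- msw + runif(1, 0.01, 3)
    n0 <- runif(1, 1.5, 8)
    expect_lt(genetic_determination_g2(msb, msw, n0),
              intraclass_r(msb, msw, n0))
  }
})

test_that("diet ICC grows with the planted diet effect", {
  iccs <- sapply(c(0, 0.3, 0.8, 1.5), function(eff) {
    cfg <- sim_config(n_genes = 40, seed = 42, sigma2_diet = eff^2 / 2,
                      diet_affected_frac = 1, sigma2_batch = 0)
    s <- simulate_dataset(cfg)
    mean(sapply(1:40, function(g)
      diet_icc(s$dataset$values[g, ], s$dataset$metadata)))
  })
  expect_lt(abs(iccs[1]), 0.05)
  expect_true(all(diff(iccs) > 0))
  one <- make_toy_dataset(matrix(rnorm(12), 2, 6),
                          meta = within(make_meta(6), diet <- "HP"))
  expect_error(diet_icc(one$values[1, ], one$metadata), "both diets")
})

test_that("heritability table recovers planted ICC and keeps g2 below r_I", {
  for (icc in c(0, 0.5)) {
    cfg <- sim_config(n_genes = 150, seed = 30 + icc * 10,
                      sigma2_strain = icc, sigma2_resid = 1 - icc,
                      sigma2_interaction = 0, sigma2_batch = 0,
                      diet_affected_frac = 0)
    s <- simulate_dataset(cfg)
    h <- heritability_all(s$dataset)
    expect_lt(abs(mean(h$ri_full) - icc), 0.05)
    up <- h$msb_full > h$msw_full
    expect_true(all(h$g2_full[up] < h$ri_full[up]))
  }
})

test_that("summary statistics match hand quartiles on a fixed vector", {
  herit <- data.frame(feature_id = sprintf("f%d", 1:5),
                      ri_full = c(0.1, 0.3, 0.2, 0.5, 0.4))
  sm <- summarize_heritability(herit, metrics = "ri_full")
  expect_equal(sm$median, 0.3)
  expect_equal(sm$q1, 0.2)
  expect_equal(sm$q3, 0.4)
  expect_equal(sm$min, 0.1)
  expect_equal(sm$max, 0.5)
  expect_equal(sm$mean, 0.3)
  expect_equal(sm$se, sd(herit$ri_full) / sqrt(5))
})

test_that("distribution comparison: MWU matches exhaustive enumeration", {
  set.seed(3)
  x <- rnorm(4); y <- rnorm(4)
  res <- compare_g2_distributions(x, y)
  expect_equal(res$mwu_stat, oracle_mwu_u(x, y), tolerance = 1e-12)
  # identical vectors: D = 0 region, MWU p in the no-evidence region
  same <- c(0.1, 0.2, 0.35, 0.4, 0.41, 0.6)
  r2 <- compare_g2_distributions(same, same)
  expect_equal(r2$ks_stat, 0)
  expect_gt(r2$mwu_p, 0.9)
  # disjoint supports: D = 1
  r3 <- compare_g2_distributions(1:5, 11:15)
  expect_equal(r3$ks_stat, 1)
})

test_that("REML variance partition agrees with lme4 and sums POV to 100", {
  cfg <- sim_config(n_genes = 6, seed = 4, sigma2_strain = 0.3,
                    sigma2_diet = 0.05, diet_affected_frac = 1,
                    sigma2_interaction = 0.1, sigma2_batch = 0,
                    sigma2_resid = 0.4)
  s <- simulate_dataset(cfg)
  meta <- s$dataset$metadata
  d <- data.frame(strain = meta$strain, diet = meta$diet)
  for (g in 1:6) {
    y <- s$dataset$values[g, ]
    mine <- partition_variance(y, meta)
    d$y <- y
    fit <- suppressMessages(lme4::lmer(
      y ~ 1 + (1 | strain) + (1 | diet) + (1 | strain:diet), data = d,
      REML = TRUE,
      control = lme4::lmerControl(check.conv.singular = "ignore")))
    vc <- as.data.frame(lme4::VarCorr(fit))
    ref <- setNames(vc$vcov, vc$grp)
    expect_equal(mine$sigma2_strain, unname(ref["strain"]), tolerance = 2e-3)
    expect_equal(mine$sigma2_interaction, unname(ref["strain:diet"]),
                 tolerance = 2e-3)
    expect_equal(mine$sigma2_resid, unname(ref["Residual"]), tolerance = 2e-3)
    expect_equal(mine$pov_strain + mine$pov_diet + mine$pov_interaction +
                   mine$pov_resid, 100, tolerance = 1e-6)
  }
})

test_that("balanced designs: REML equals expected-mean-squares estimates", {
  # interior (well-separated) components on a balanced design
  set.seed(5)
  cfg <- sim_config(n_strains = 10, reps_per_cell = 4, n_genes = 4, seed = 5,
                    sigma2_strain = 1, sigma2_diet = 0.5,
                    diet_affected_frac = 1, sigma2_interaction = 0.6,
                    sigma2_batch = 0, sigma2_resid = 0.05)
  s <- simulate_dataset(cfg)
  meta <- s$dataset$metadata
  for (g in 1:4) {
    y <- s$dataset$values[g, ]
    mom <- oracle_mom_components(y, meta$strain, meta$diet)
    mine <- partition_variance(y, meta)
    if (all(mom[1:3] > 0.01)) {
      expect_equal(mine$sigma2_strain, unname(mom["strain"]), tolerance = 1e-5)
      expect_equal(mine$sigma2_diet, unname(mom["diet"]), tolerance = 1e-5)
      expect_equal(mine$sigma2_interaction, unname(mom["interaction"]),
                   tolerance = 1e-5)
      expect_equal(mine$sigma2_resid, unname(mom["resid"]), tolerance = 1e-5)
    }
  }
})

test_that("null strain and interaction components partition near zero", {
  cfg <- sim_config(n_genes = 40, seed = 6, sigma2_strain = 0,
                    sigma2_diet = 0, diet_affected_frac = 0,
                    sigma2_interaction = 0, sigma2_batch = 0,
                    sigma2_resid = 0.2)
  s <- simulate_dataset(cfg)
  pv <- partition_variance_all(s$dataset)
  expect_true(all(pv$converged))
  expect_lt(mean(pv$pov_strain), 2)
  expect_lt(mean(pv$pov_interaction), 2)
})

test_that("one observation per cell: interaction is shrunk toward zero", {
  cfg <- sim_config(n_strains = 12, reps_per_cell = 1, n_genes = 10, seed = 7,
                    sigma2_strain = 0.4, sigma2_diet = 0,
                    diet_affected_frac = 0, sigma2_interaction = 0.2,
                    sigma2_batch = 0, sigma2_resid = 0.3)
  s <- simulate_dataset(cfg)
  pv <- partition_variance_all(s$dataset)
  # interaction is confounded with residual in this design; documented
  # behaviour is a near-zero interaction estimate, not an error
  expect_true(all(is.finite(pv$pov_interaction[pv$converged])))
  expect_lt(mean(pv$pov_interaction[pv$converged]), 15)
})
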