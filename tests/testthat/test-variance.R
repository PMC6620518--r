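test_that("effect model preconditions reject degenerate designs", {
  tr <- generator_truth(5, sigma_residual = 0.1, seed = 1)
  tab <- gen_score_table(tr, n_reps = 3)
  expect_error(fit_effect_model(tab), ">= 2 conditions")
  tab2 <- gen_score_table(tr, n_reps = 2, conditions = c("a", "b"))
  expect_error(fit_effect_model(tab2[-1, ]), "unbalanced")
})

test_that("a strong condition shift is detected, a zero shift mostly is not", {
  tr <- generator_truth(10, sigma_sample = 1, sigma_residual = 0.2, seed = 7)
  shifted <- gen_score_table(tr, n_reps = 3, conditions = c("0%", "30%"),
                             condition_effects = c(0, 3 * 0.2))
  fit <- fit_effect_model(shifted)
  expect_lt(fit$p_value, 0.05)
  expect_equal(diff(unname(fit$condition_effects)), 0.6, tolerance = 0.15)

  # under the null, p is roughly uniform: check a loose band over 100 sims
  ps <- vapply(1:100, function(s) {
    trs <- generator_truth(8, sigma_sample = 1, sigma_residual = 0.3,
                           seed = 1000 + s)
    fit_effect_model(gen_score_table(trs, n_reps = 2,
                                     conditions = c("a", "b")))$p_value
  }, numeric(1))
  expect_gt(mean(ps < 0.05), 0)   # not degenerate at 0
  expect_lt(mean(ps < 0.05), 0.15)
})

test_that("zero residual variance leaves the p-value undefined", {
  tr <- generator_truth(4, sigma_sample = 1, seed = 3)  # all noise SDs 0
  tab <- gen_score_table(tr, n_reps = 2, conditions = c("a", "b"),
                         condition_effects = c(0, 1))
  fit <- fit_effect_model(tab)
  expect_true(is.na(fit$p_value))
})

test_that("zero-noise tables give exactly zero variance components", {
  tr <- generator_truth(5, sigma_sample = 0.8, seed = 11)
  tab <- gen_score_table(tr, n_runs = 3, n_reps = 3)
  vc <- estimate_variance_components(tab)
  expect_equal(vc$sigma2_run, 0)
  expect_equal(vc$sigma2_interaction, 0)
  expect_equal(vc$sigma2_residual, 0)
  expect_equal(vc$intra_run_sd, 0)
  expect_equal(vc$inter_run_sd, 0)
})

test_that("components match a REML likelihood fit on a balanced instance", {
  skip_if_not_installed("lme4")
  tr <- generator_truth(6, sigma_sample = 1, sigma_run = 0.5,
                        sigma_interaction = 0.4, sigma_residual = 0.3,
                        seed = 17)
  tab <- gen_score_table(tr, n_runs = 4, n_reps = 3)
  vc <- estimate_variance_components(tab)
  fit <- suppressMessages(
    lme4::lmer(score ~ 0 + sample_id + (1 | run_id) +
                 (1 | sample_id:run_id), data = tab))
  v <- as.data.frame(lme4::VarCorr(fit))
  reml <- c(run = v$vcov[v$grp == "run_id"],
            inter = v$vcov[v$grp == "sample_id:run_id"],
            res = v$vcov[v$grp == "Residual"])
  expect_equal(vc$sigma2_run, unname(reml["run"]), tolerance = 1e-4)
  expect_equal(vc$sigma2_interaction, unname(reml["inter"]), tolerance = 1e-4)
  expect_equal(vc$sigma2_residual, unname(reml["res"]), tolerance = 1e-4)
})

test_that("inestimable components are reported absent, not zero", {
  tr <- generator_truth(4, sigma_sample = 1, sigma_residual = 0.2, seed = 5)
  one_run <- gen_score_table(tr, n_runs = 1, n_reps = 3)
  vc1 <- estimate_variance_components(one_run)
  expect_true(is.na(vc1$sigma2_run))
  expect_false(is.na(vc1$sigma2_residual))
  expect_true(is.na(vc1$inter_run_sd))

  one_rep <- gen_score_table(tr, n_runs = 3, n_reps = 1)
  vc2 <- estimate_variance_components(one_rep)
  expect_true(is.na(vc2$sigma2_residual))
})

test_that("inter-run SD dominates intra-run SD and shifts cancel", {
  tr <- generator_truth(8, sigma_sample = 1, sigma_run = 0.2,
                        sigma_interaction = 0.15, sigma_residual = 0.1,
                        seed = 19)
  tab <- gen_score_table(tr, n_runs = 3, n_reps = 3)
  vc <- estimate_variance_components(tab)
  expect_gte(vc$inter_run_sd, vc$intra_run_sd)
  tab2 <- tab
  tab2$score <- tab2$score + 100
  vc2 <- estimate_variance_components(tab2)
  expect_equal(vc2$intra_run_sd, vc$intra_run_sd)
  expect_equal(vc2$inter_run_sd, vc$inter_run_sd)
})

test_that("pooled SD matches its textbook cases and the residual identity", {
  expect_equal(pooled_sd(list(c(1, 1), c(2, 2))), 0)
  expect_equal(pooled_sd(list(c(0, 2))), sqrt(2))
  expect_true(is.na(pooled_sd(list(1, 2, 3))))
  tr <- generator_truth(6, sigma_sample = 1, sigma_run = 0.3,
                        sigma_interaction = 0.2, sigma_residual = 0.25,
                        seed = 23)
  tab <- gen_score_table(tr, n_runs = 3, n_reps = 3)
  vc <- estimate_variance_components(tab)
  cells <- split(tab$score, interaction(tab$sample_id, tab$run_id))
  expect_equal(pooled_sd(cells), vc$intra_run_sd)
})

test_that("the estimator matches a manual decomposition with known effects", {
  mu <- c(0.5, -1, 2)
  r_eff <- c(0.3, -0.3)
  inter <- matrix(c(0.1, -0.1, 0.05, -0.05, 0.2, -0.2), 3, 2, byrow = TRUE)
  eps <- array(withr::with_seed(31, stats::rnorm(12, 0, 0.1)), c(3, 2, 2))
  tab <- manual_vc_table(mu, r_eff, inter, eps)
  vc <- estimate_variance_components(tab)
  an <- stats::anova(stats::lm(score ~ sample_id * run_id, data = tab))
  ms <- an[["Mean Sq"]]
  expect_equal(vc$sigma2_residual, ms[4])
  expect_equal(vc$sigma2_interaction, max(0, (ms[3] - ms[4]) / 2))
  expect_equal(vc$sigma2_run, max(0, (ms[2] - ms[3]) / 6))
})

test_that("bootstrap CIs are seed-reproducible and degenerate at zero noise", {
  tr <- generator_truth(5, sigma_sample = 1, sigma_run = 0.2,
                        sigma_interaction = 0.1, sigma_residual = 0.15,
                        seed = 29)
  tab <- gen_score_table(tr, n_runs = 3, n_reps = 3)
  ci1 <- bootstrap_sd_ci(tab, "intra_run_sd", B = 300, seed = 4)
  ci2 <- bootstrap_sd_ci(tab, "intra_run_sd", B = 300, seed = 4)
  expect_identical(ci1$ci, ci2$ci)
  expect_identical(ci1$boot, ci2$boot)

  # a function statistic resampling the same quantity agrees exactly
  ci_fn <- bootstrap_sd_ci(tab, function(t) {
    estimate_variance_components(t)$intra_run_sd
  }, B = 300, seed = 4)
  expect_equal(ci_fn$ci, ci1$ci)

  quiet <- gen_score_table(generator_truth(4, sigma_sample = 1, seed = 2),
                           n_runs = 3, n_reps = 2)
  ci0 <- bootstrap_sd_ci(quiet, "intra_run_sd", B = 200, seed = 1)
  expect_equal(ci0$ci, c(0, 0))
  expect_equal(ci0$estimate, 0)
})

test_that("inter-class SD pools per-sample means across both classes", {
  tr <- generator_truth(4, class_mean_separation = 2, sigma_sample = 0,
                        seed = 13)
  tab <- gen_score_table(tr, n_reps = 3)
  # sample means are exactly +/-1: SD over 8 samples = sqrt(8/7)
  expect_equal(inter_class_sd(tab), sqrt(8 / 7))
})

test_that("interlab analysis handles the paired two-lab contract", {
  tr <- generator_truth(20, class_mean_separation = 4, sigma_sample = 1.2,
                        sigma_residual = 0.13, seed = 37)
  tab <- gen_score_table(tr, n_labs = 2)
  res <- interlab_analysis(tab, threshold = 0, B = 300, seed = 2)
  expect_equal(res$n_pairs, 40)
  expect_gt(res$r_squared, 0.95)
  expect_lt(abs(res$pooled_sd - 0.13), 0.05)
  expect_true(res$ci[1] <= res$pooled_sd && res$pooled_sd <= res$ci[2])

  # identical labs
  tab0 <- gen_score_table(generator_truth(10, sigma_sample = 1, seed = 3),
                          n_labs = 2)
  res0 <- interlab_analysis(tab0, threshold = 0, B = 0)
  expect_equal(res0$concordance, 1)
  expect_equal(res0$pooled_sd, 0)
  expect_equal(res0$r_squared, 1)

  # three labs rejected
  tab3 <- gen_score_table(generator_truth(5, sigma_sample = 1, seed = 3),
                          n_labs = 3)
  expect_error(interlab_analysis(tab3), "two labs")

  # unpaired samples are excluded with a warning
  tab_un <- tab[-1, ]
  expect_warning(res_un <- interlab_analysis(tab_un, threshold = 0, B = 0),
                 "excluded")
  expect_equal(res_un$n_pairs, 39)
})
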