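test_that("count matrix and score table TSVs round-trip", {
  m <- gen_count_matrix(40, 5, n_informative = 10, seed = 51)
  d <- withr::local_tempdir()
  write_count_matrix(m, file.path(d, "counts.tsv"), file.path(d, "meta.tsv"))
  back <- read_count_matrix(file.path(d, "counts.tsv"),
                            file.path(d, "meta.tsv"))
  expect_equal(back$counts, m$counts)
  expect_equal(back$meta, m$meta)

  tr <- generator_truth(5, sigma_sample = 1, sigma_residual = 0.1, seed = 52)
  tab <- gen_score_table(tr, n_runs = 2, n_reps = 2)
  write_score_table(tab, file.path(d, "scores.tsv"))
  tab2 <- read_score_table(file.path(d, "scores.tsv"))
  expect_equal(tab2$score, tab$score)
  expect_identical(tab2$sample_id, tab$sample_id)

  f <- size_factors(m$counts + 1)
  write_size_factors(f, file.path(d, "sf.tsv"))
  sf <- utils::read.delim(file.path(d, "sf.tsv"))
  expect_equal(sf$factor, unname(f))
})

test_that("configuration validation fills defaults and rejects bad input", {
  cfg <- validate_config(list(study = "spec"))
  expect_s3_class(cfg, "study_config")
  expect_equal(cfg$spec$grid_min, 0.36)
  expect_equal(cfg$spec$grid_max, 2.10)
  expect_equal(cfg$spec$grid_step, 0.02)
  expect_equal(cfg$spec$reps, 1000)
  expect_equal(cfg$bootstrap$B, 2000)
  expect_equal(cfg$vaf_threshold, 0.05)
  # empty requirements fall back to the rule-out defaults
  cfg2 <- validate_config(list(study = "spec",
                               spec = list(requirements = list())))
  expect_equal(unlist(cfg2$spec$requirements),
               c(sensitivity = 0.90, npv = 0.90))

  expect_error(validate_config(list(studyy = "spec")), "studyy")
  expect_error(validate_config(list(study = "spec",
                                    spec = list(grid_step = 0))),
               "grid_step")
  expect_error(validate_config(list(input = list(score_table = "nope.tsv"))),
               "score_table")
  expect_error(validate_config(list(study = "everything")), "study")
})

test_that("YAML configs parse the same as lists", {
  cfg <- validate_config("study: repro\nseed: 9\ngenerator:\n  n_runs: 2\n")
  expect_identical(cfg$study, "repro")
  expect_equal(cfg$seed, 9)
  expect_equal(cfg$generator$n_runs, 2)
})

test_that("a repro study runs end to end and reports variance components", {
  d <- withr::local_tempdir()
  res <- suppressMessages(run_study(list(
    study = "repro", seed = 5, out_dir = d,
    generator = list(n_samples_per_class = 6),
    bootstrap = list(B = 200))))
  expect_true(file.exists(file.path(d, "results.json")))
  expect_true(file.exists(file.path(d, "summary.txt")))
  expect_true(file.exists(file.path(d, "repro_scores.tsv")))
  expect_gt(res$repro$intra_run_sd, 0)
  expect_gte(res$repro$inter_run_sd, res$repro$intra_run_sd)
  expect_length(res$repro$intra_run_ci, 2)
})

test_that("identical configs give byte-identical results", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  base <- list(study = "spec", seed = 3,
               generator = list(n_samples_per_class = 5),
               spec = list(grid_min = 0.4, grid_max = 0.6, grid_step = 0.1,
                           reps = 100))
  suppressMessages(run_study(c(base, list(out_dir = d1))))
  suppressMessages(run_study(c(base, list(out_dir = d2))))
  expect_identical(readLines(file.path(d1, "results.json")),
                   readLines(file.path(d2, "results.json")))
  expect_identical(readLines(file.path(d1, "noise_grid_medians.tsv")),
                   readLines(file.path(d2, "noise_grid_medians.tsv")))
})

test_that("a full synthetic study completes with coherent stage outputs", {
  d <- withr::local_tempdir()
  res <- suppressMessages(run_study(list(
    study = "full", seed = 7, out_dir = d,
    generator = list(n_samples_per_class = 5, n_genes = 150,
                     n_informative = 40, effect_size = 2.5,
                     dispersion = 0.05),
    spec = list(grid_min = 0.36, grid_max = 0.8, grid_step = 0.04,
                reps = 100),
    bootstrap = list(B = 200))))
  expect_named(res, c("config", "repro", "effects", "lod", "interference",
                      "spec"))
  expect_true(res$lod$control_pass)
  expect_false(is.na(res$lod$in_silico_lod))
  # the fine in-silico grid never reports a worse LOD than the coarse ladder
  expect_lte(res$lod$in_silico_lod * 100, res$lod$in_vitro_lod)
  expect_true(res$effects$p_value > 0 || is.na(res$effects$p_value))
  expect_true(res$interference$baseline_pass)
  expect_true(file.exists(file.path(d, "lod_series.tsv")))
  expect_true(file.exists(file.path(d, "interference_titration.tsv")))
})

test_that("a failing stage leaves a FAILED marker and names the stage", {
  d <- withr::local_tempdir()
  scores <- file.path(d, "bad_scores.tsv")
  writeLines("sample_id\ttrue_class\tcondition\trun_id\tlab_id\treplicate_id\tscore",
             scores)
  cfg <- list(study = "repro", seed = 1, out_dir = d,
              input = list(score_table = scores))
  expect_error(suppressMessages(run_study(cfg)), "repro")
  expect_true(file.exists(file.path(d, "FAILED")))
})
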