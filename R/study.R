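#' Validate a study configuration
#'
#' Parses and validates the structured (YAML) configuration driving
#' [run_study()]. Unknown keys are rejected by name; type and range
#' violations are collected and reported as an itemized list. Defaults are
#' filled for everything optional: noise grid 0.36-2.10 step 0.02 with 1000
#' replicates, bootstrap `B = 2000`, VAF threshold 0.05, and requirements
#' sensitivity >= 0.90 and NPV >= 0.90.
#'
#' @param config path to a YAML file, a YAML string, or a list.
#' @return a validated `study_config` list.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    raw <- if (file.exists(config)) {
      yaml::read_yaml(config)
    } else {
      yaml::yaml.load(config)
    }
  } else if (is.list(config)) {
    raw <- config
  } else {
    abort("`config` must be a path, YAML text, or a list")
  }
  if (is.null(raw)) raw <- list()
  errs <- character()
  note <- function(fmt, ...) errs[[length(errs) + 1L]] <<- sprintf(fmt, ...)

  known <- c("study", "seed", "out_dir", "input", "generator", "lod",
             "interference", "effects", "spec", "bootstrap",
             "vaf_threshold", "prevalence")
  extra <- setdiff(names(raw), known)
  if (length(extra)) note("unknown key(s): %s", paste(extra, collapse = ", "))

  cfg <- list()
  cfg$study <- raw$study %||% "full"
  if (!cfg$study %in% c("lod", "interference", "effects", "repro", "spec",
                        "full")) {
    note("`study` must be one of lod, interference, effects, repro, spec, full")
  }
  cfg$seed <- raw$seed %||% 1L
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L) {
    note("`seed` must be a single integer")
  }
  cfg$out_dir <- raw$out_dir %||% "assayval-results"
  if (!is.character(cfg$out_dir) || length(cfg$out_dir) != 1L) {
    note("`out_dir` must be a single path")
  }

  inp <- raw$input %||% list()
  extra <- setdiff(names(inp), c("score_table", "counts", "meta"))
  if (length(extra)) note("unknown input key(s): %s",
                          paste(extra, collapse = ", "))
  for (k in names(inp)) {
    if (!is.character(inp[[k]]) || !file.exists(inp[[k]])) {
      note("input `%s`: path does not exist (%s)", k, inp[[k]])
    }
  }
  cfg$input <- inp

  gen_keys <- c("n_samples_per_class", "class_mean_separation",
                "sigma_sample", "sigma_run", "sigma_interaction",
                "sigma_residual", "score_range", "n_runs", "n_reps",
                "n_labs", "n_genes", "n_informative", "effect_size",
                "dispersion", "libsize_cv")
  gen <- raw$generator %||% list()
  extra <- setdiff(names(gen), gen_keys)
  if (length(extra)) note("unknown generator key(s): %s",
                          paste(extra, collapse = ", "))
  defaults <- list(n_samples_per_class = 8, class_mean_separation = 4,
                   sigma_sample = 1, sigma_run = 0.1875,
                   sigma_interaction = 0.1875, sigma_residual = 0.069,
                   score_range = 8, n_runs = 3, n_reps = 3, n_labs = 1,
                   n_genes = 600, n_informative = 60, effect_size = 1.5,
                   dispersion = 0.1, libsize_cv = 0.2)
  cfg$generator <- utils::modifyList(defaults, gen)
  for (k in c("sigma_sample", "sigma_run", "sigma_interaction",
              "sigma_residual")) {
    v <- cfg$generator[[k]]
    if (!is.numeric(v) || v < 0) note("generator `%s` must be >= 0", k)
  }

  lod <- raw$lod %||% list()
  extra <- setdiff(names(lod), c("grid_step", "in_vitro_levels"))
  if (length(extra)) note("unknown lod key(s): %s",
                          paste(extra, collapse = ", "))
  cfg$lod <- utils::modifyList(
    list(grid_step = 0.01, in_vitro_levels = c(0, 40, 60, 80, 100)), lod)
  gs <- cfg$lod$grid_step
  if (!is.numeric(gs) || length(gs) != 1L || gs <= 0 || gs > 1 ||
      abs(1 / gs - round(1 / gs)) > 1e-8) {
    note("lod `grid_step` must be in (0, 1] and divide 1 evenly")
  }

  itf <- raw$interference %||% list()
  extra <- setdiff(names(itf), c("kind", "levels"))
  if (length(extra)) note("unknown interference key(s): %s",
                          paste(extra, collapse = ", "))
  cfg$interference <- utils::modifyList(
    list(kind = "blood", levels = c(0, 25, 50, 75, 100)), itf)
  if (!cfg$interference$kind %in% c("blood", "gDNA")) {
    note("interference `kind` must be 'blood' or 'gDNA'")
  }
  lv <- cfg$interference$levels
  if (!is.numeric(lv) || !0 %in% lv || any(lv < 0 | lv > 100)) {
    note("interference `levels` must be percentages in [0, 100] including 0")
  }

  eff <- raw$effects %||% list()
  extra <- setdiff(names(eff), c("conditions", "condition_effects", "n_reps"))
  if (length(extra)) note("unknown effects key(s): %s",
                          paste(extra, collapse = ", "))
  cfg$effects <- utils::modifyList(
    list(conditions = c("5ng", "10ng", "15ng", "20ng", "30ng"),
         condition_effects = NULL, n_reps = 3), eff)

  spc <- raw$spec %||% list()
  extra <- setdiff(names(spc), c("grid_min", "grid_max", "grid_step", "reps",
                                 "requirements"))
  if (length(extra)) note("unknown spec key(s): %s",
                          paste(extra, collapse = ", "))
  cfg$spec <- utils::modifyList(
    list(grid_min = 0.36, grid_max = 2.10, grid_step = 0.02, reps = 1000,
         requirements = list(sensitivity = 0.90, npv = 0.90)), spc)
  if (length(cfg$spec$requirements) == 0) {
    cfg$spec$requirements <- list(sensitivity = 0.90, npv = 0.90)
  }
  if (!is.numeric(cfg$spec$grid_step) || cfg$spec$grid_step <= 0) {
    note("spec `grid_step` must be > 0")
  } else if (cfg$spec$grid_max < cfg$spec$grid_min) {
    note("spec grid: `grid_max` must be >= `grid_min`")
  }
  if (!is.numeric(cfg$spec$reps) || cfg$spec$reps < 1) {
    note("spec `reps` must be >= 1")
  }
  req <- unlist(cfg$spec$requirements)
  if (is.null(names(req)) || any(req < 0 | req > 1)) {
    note("spec `requirements` must be named proportions in [0, 1]")
  }

  bt <- raw$bootstrap %||% list()
  extra <- setdiff(names(bt), "B")
  if (length(extra)) note("unknown bootstrap key(s): %s",
                          paste(extra, collapse = ", "))
  cfg$bootstrap <- utils::modifyList(list(B = 2000), bt)
  if (!is.numeric(cfg$bootstrap$B) || cfg$bootstrap$B < 200) {
    note("bootstrap `B` must be >= 200")
  }

  cfg$vaf_threshold <- raw$vaf_threshold %||% 0.05
  if (!is.numeric(cfg$vaf_threshold) || cfg$vaf_threshold < 0 ||
      cfg$vaf_threshold > 1) {
    note("`vaf_threshold` must lie in [0, 1]")
  }
  cfg$prevalence <- raw$prevalence
  if (!is.null(cfg$prevalence) &&
      (!is.numeric(cfg$prevalence) || cfg$prevalence <= 0 ||
       cfg$prevalence >= 1)) {
    note("`prevalence` must lie in (0, 1)")
  }

  if (length(errs)) {
    abort("invalid study configuration:\n%s",
          paste0("  - ", errs, collapse = "\n"))
  }
  structure(cfg, class = "study_config")
}

study_log <- function(level, fmt, ...) {
  message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
}

#' Run a validation study end to end
#'
#' Executes the requested study arm(s) in dependency order — generate (or
#' load) inputs, normalize, train and score the surrogate, analyze — writing
#' every stage table as TSV plus a human-readable `summary.txt` and a
#' machine-readable `results.json` into the configured output directory.
#' Identical configuration and seed give byte-identical numeric results. A
#' stage failure aborts with the stage name; partial outputs are retained
#' next to a `FAILED` marker file.
#'
#' @param config a `study_config` from [validate_config()], or anything it
#'   accepts.
#' @return invisibly, the named list of stage results (also serialized to
#'   `results.json`).
#' @export
run_study <- function(config) {
  cfg <- if (inherits(config, "study_config")) config else validate_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- if (cfg$study == "full") {
    c("repro", "effects", "lod", "interference", "spec")
  } else {
    cfg$study
  }
  results <- list(config = unclass(cfg)[c("study", "seed", "vaf_threshold")])
  for (st in stages) {
    study_log("INFO", "stage `%s` starting (seed %d)", st, cfg$seed)
    results[[st]] <- tryCatch(
      switch(st,
             repro = stage_repro(cfg),
             effects = stage_effects(cfg),
             lod = stage_lod(cfg),
             interference = stage_interference(cfg),
             spec = stage_spec(cfg)),
      error = function(e) {
        writeLines(sprintf("stage `%s` failed: %s", st, conditionMessage(e)),
                   file.path(cfg$out_dir, "FAILED"))
        abort("stage `%s` failed: %s", st, conditionMessage(e))
      })
    study_log("INFO", "stage `%s` done", st)
  }
  jsonlite::write_json(results, file.path(cfg$out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  writeLines(summarize_results(results),
             file.path(cfg$out_dir, "summary.txt"))
  invisible(results)
}

# -- stages -----------------------------------------------------------------

study_truth <- function(cfg, seed_offset = 0L) {
  g <- cfg$generator
  generator_truth(n_samples_per_class = g$n_samples_per_class,
                  class_mean_separation = g$class_mean_separation,
                  sigma_sample = g$sigma_sample, sigma_run = g$sigma_run,
                  sigma_interaction = g$sigma_interaction,
                  sigma_residual = g$sigma_residual,
                  score_range = g$score_range,
                  seed = cfg$seed + seed_offset)
}

study_score_table <- function(cfg, seed_offset = 0L, ...) {
  if (!is.null(cfg$input$score_table)) {
    read_score_table(cfg$input$score_table)
  } else {
    g <- cfg$generator
    gen_score_table(study_truth(cfg, seed_offset), n_runs = g$n_runs,
                    n_reps = g$n_reps, n_labs = g$n_labs, ...)
  }
}

study_count_matrix <- function(cfg, seed_offset = 0L) {
  if (!is.null(cfg$input$counts)) {
    if (is.null(cfg$input$meta)) abort("`input$counts` needs `input$meta`")
    read_count_matrix(cfg$input$counts, cfg$input$meta)
  } else {
    g <- cfg$generator
    gen_count_matrix(n_genes = g$n_genes,
                     n_per_class = max(10, g$n_samples_per_class),
                     n_informative = g$n_informative,
                     effect_size = g$effect_size,
                     dispersion = g$dispersion, libsize_cv = g$libsize_cv,
                     seed = cfg$seed + seed_offset)
  }
}

stage_repro <- function(cfg) {
  tab <- study_score_table(cfg, seed_offset = 11L)
  write_score_table(tab, file.path(cfg$out_dir, "repro_scores.tsv"))
  vc <- estimate_variance_components(tab)
  B <- cfg$bootstrap$B
  ci_intra <- bootstrap_sd_ci(tab, "intra_run_sd", B = B,
                              seed = cfg$seed + 12L)
  ci_inter <- bootstrap_sd_ci(tab, "inter_run_sd", B = B,
                              seed = cfg$seed + 13L)
  list(intra_run_sd = vc$intra_run_sd, intra_run_ci = ci_intra$ci,
       inter_run_sd = vc$inter_run_sd, inter_run_ci = ci_inter$ci,
       sigma2_run = vc$sigma2_run,
       sigma2_interaction = vc$sigma2_interaction,
       sigma2_residual = vc$sigma2_residual,
       design = as.list(vc$design), bootstrap_B = B,
       conventions = list(
         inter_run_sd = "sqrt(run + interaction + residual variance)",
         bootstrap = "whole-sample block resampling, percentile CI"))
}

stage_effects <- function(cfg) {
  e <- cfg$effects
  if (!is.null(cfg$input$score_table)) {
    tab <- read_score_table(cfg$input$score_table)
  } else {
    g <- cfg$generator
    tab <- gen_score_table(study_truth(cfg, 21L), n_runs = 1,
                           n_reps = e$n_reps,
                           conditions = e$conditions,
                           condition_effects = e$condition_effects)
  }
  write_score_table(tab, file.path(cfg$out_dir, "effects_scores.tsv"))
  fit <- fit_effect_model(tab, "condition")
  list(conditions = names(fit$condition_effects),
       condition_effects = unname(fit$condition_effects),
       f_statistic = fit$f_statistic, p_value = fit$p_value,
       sigma2_sample = fit$sigma2_sample,
       sigma2_residual = fit$sigma2_residual)
}

stage_lod <- function(cfg) {
  train <- study_count_matrix(cfg, 31L)
  model <- train_classifier(normalize_counts(train),
                            train$meta$true_class)
  g <- cfg$generator
  test <- gen_count_matrix(n_genes = g$n_genes, n_per_class = 1,
                           n_informative = g$n_informative,
                           effect_size = g$effect_size,
                           dispersion = g$dispersion,
                           libsize_cv = g$libsize_cv, seed = cfg$seed + 32L)
  pos <- test$counts[, test$meta$true_class == "positive"]
  neg <- test$counts[, test$meta$true_class == "negative"]
  series <- in_silico_titration(pos, neg, model,
                                grid_step = cfg$lod$grid_step)
  write_mixture_series(series, file.path(cfg$out_dir, "lod_series.tsv"))
  write_classifier(model, file.path(cfg$out_dir, "classifier.tsv"))
  # coarse in-vitro design read off the same series: dilution d% of the
  # negative parent corresponds to positive fraction (100 - d)/100
  lv <- sort(cfg$lod$in_vitro_levels)
  p_at <- (100 - lv) / 100
  calls <- vapply(p_at, function(p) {
    series$points$call[which.min(abs(series$points$p - p))]
  }, character(1))
  iv <- in_vitro_lod(lv, calls)
  list(in_silico_lod = series$lod, control_pass = series$control_pass,
       in_vitro_lod = iv$lod, tolerated_dilution = iv$tolerated_dilution,
       grid_step = cfg$lod$grid_step,
       normalization = series$normalization$mode)
}

stage_interference <- function(cfg) {
  m <- study_count_matrix(cfg, 41L)
  model <- train_classifier(normalize_counts(m), m$meta$true_class)
  g <- cfg$generator
  prof <- gen_interference_profile(cfg$interference$kind, g$n_genes,
                                   seed = cfg$seed + 42L)
  prof <- stats::setNames(as.numeric(prof), names(prof))
  test <- gen_count_matrix(n_genes = g$n_genes, n_per_class = 1,
                           n_informative = g$n_informative,
                           effect_size = g$effect_size,
                           dispersion = g$dispersion,
                           libsize_cv = g$libsize_cv, seed = cfg$seed + 43L)
  pos <- test$counts[, test$meta$true_class == "positive"]
  lv <- sort(cfg$interference$levels)
  fr <- lv / 100
  contaminated <- vapply(fr, function(f) {
    make_contaminated(pos, prof, f)
  }, numeric(length(pos)))
  rownames(contaminated) <- names(pos)
  colnames(contaminated) <- sprintf("lvl%03d", lv)
  sf <- size_factors(cbind(contaminated, .sample = pos,
                           .interferent = prof + 1e-9))
  norm <- normalize_counts(cbind(contaminated, .sample = pos,
                                 .interferent = prof + 1e-9), sf)
  scored <- score_samples(model, norm[, colnames(contaminated), drop = FALSE])
  utils::write.table(
    data.frame(level = lv, score = scored$score, call = scored$call),
    file.path(cfg$out_dir, "interference_titration.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  fit <- if (length(unique(fr)) >= 4) {
    fit_sigmoid(fr, scored$score, threshold = model$threshold)
  } else {
    NULL
  }
  mt <- max_tolerated_level(lv, scored$call, expected_class = "positive")
  list(kind = cfg$interference$kind, levels = lv,
       scores = scored$score, calls = scored$call,
       max_tolerated_level = mt$max_level,
       baseline_pass = mt$baseline_pass,
       sigmoid = if (!is.null(fit)) list(
         lower = fit$lower, upper = fit$upper, inflection = fit$inflection,
         slope = fit$slope, crossing = fit$crossing,
         degenerate = fit$degenerate) else NULL)
}

stage_spec <- function(cfg) {
  tab <- study_score_table(cfg, 51L)
  per_sample <- stats::aggregate(score ~ sample_id + true_class, data = tab,
                                 FUN = mean)
  sp <- cfg$spec
  grid <- seq(sp$grid_min, sp$grid_max, by = sp$grid_step)
  nt <- simulate_noise_grid(per_sample$score, per_sample$true_class,
                            threshold = attr(tab, "threshold") %||% 0,
                            grid = grid, reps = sp$reps,
                            prevalence = cfg$prevalence,
                            seed = cfg$seed + 52L)
  utils::write.table(nt$medians,
                     file.path(cfg$out_dir, "noise_grid_medians.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  spec <- determine_sd_spec(nt, requirements = unlist(sp$requirements))
  list(sd_spec = spec$sd_spec, status = spec$status,
       requirements = as.list(unlist(sp$requirements)),
       grid = c(min = sp$grid_min, max = sp$grid_max, step = sp$grid_step),
       reps = sp$reps, prevalence = nt$prevalence)
}

summarize_results <- function(res) {
  out <- c("assayval study summary", "======================")
  fmt <- function(x, d = 4) if (is.null(x) || is.na(x)) "NA" else
    format(round(x, d), nsmall = 0)
  if (!is.null(res$repro)) {
    out <- c(out, sprintf(
      "repro: intra-run SD %s [%s, %s]; inter-run SD %s [%s, %s]",
      fmt(res$repro$intra_run_sd), fmt(res$repro$intra_run_ci[1]),
      fmt(res$repro$intra_run_ci[2]), fmt(res$repro$inter_run_sd),
      fmt(res$repro$inter_run_ci[1]), fmt(res$repro$inter_run_ci[2])))
  }
  if (!is.null(res$effects)) {
    out <- c(out, sprintf("effects: F = %s, p = %s",
                          fmt(res$effects$f_statistic),
                          fmt(res$effects$p_value)))
  }
  if (!is.null(res$lod)) {
    out <- c(out, sprintf(
      "lod: in-silico LOD %s, in-vitro LOD %s%% positive content",
      fmt(res$lod$in_silico_lod), fmt(res$lod$in_vitro_lod)))
  }
  if (!is.null(res$interference)) {
    out <- c(out, sprintf("interference (%s): max tolerated level %s%%",
                          res$interference$kind,
                          fmt(res$interference$max_tolerated_level)))
  }
  if (!is.null(res$spec)) {
    out <- c(out, sprintf("spec: SD specification %s (%s)",
                          fmt(res$spec$sd_spec), res$spec$status))
  }
  out
}
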