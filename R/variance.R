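#' Test an experimental effect on classifier scores
#'
#' Fits the additive model `score = sample effect + condition effect +
#' residual` to a balanced design in which every sample is observed under
#' every condition, and tests the fixed experimental (condition) effect by
#' the randomized-complete-block F statistic `MS(condition) / MS(residual)`
#' after removing sample means. For balanced data this F-test coincides with
#' the mixed-model test that treats the sample effect as random; unbalanced
#' designs are rejected rather than silently mis-analyzed.
#'
#' @param tab a score table (long format) with `sample_id`, `score` and the
#'   condition column.
#' @param condition_col name of the column holding the experimental
#'   condition (RNA input mass, gDNA level, laboratory, ...).
#' @return object of class `effect_fit`: condition effect estimates
#'   (deviations from the grand mean), `sigma2_sample` (method-of-moments
#'   sample-effect variance), `sigma2_residual`, `f_statistic`, `df`,
#'   `p_value` (`NA` when the residual variance is zero).
#' @export
fit_effect_model <- function(tab, condition_col = "condition") {
  need <- c("sample_id", "score", condition_col)
  miss <- setdiff(need, names(tab))
  if (length(miss)) abort("score table lacks columns: %s",
                          paste(miss, collapse = ", "))
  s <- factor(tab$sample_id)
  cond <- factor(tab[[condition_col]])
  if (nlevels(cond) < 2L) abort("need >= 2 conditions to test an effect")
  if (nlevels(s) < 2L) abort("need >= 2 samples")
  cells <- table(s, cond)
  if (any(cells == 0) || length(unique(as.vector(cells))) != 1L) {
    abort(paste("unbalanced design: every sample must be observed under",
                "every condition with equal replication; aggregate",
                "replicates to a balanced block first"))
  }
  k <- unique(as.vector(cells))
  dat <- data.frame(score = tab$score, s = s, cond = cond)
  fit <- stats::aov(score ~ s + cond, data = dat)
  an <- summary(fit)[[1]]
  rn <- trimws(rownames(an))
  ms <- an[["Mean Sq"]]; df <- an[["Df"]]
  i_s <- which(rn == "s"); i_c <- which(rn == "cond")
  i_r <- which(rn == "Residuals")
  ms_res <- ms[i_r]
  # a residual mean square at numerical zero leaves the test undefined
  zero_res <- ms_res <= 1e-12 * sum(ms)
  f_stat <- if (!zero_res) ms[i_c] / ms_res else Inf
  p <- if (!zero_res) {
    stats::pf(f_stat, df[i_c], df[i_r], lower.tail = FALSE)
  } else {
    NA_real_
  }
  cond_means <- tapply(dat$score, dat$cond, mean)
  structure(list(
    condition_effects = cond_means - mean(dat$score),
    sigma2_sample = max(0, (ms[i_s] - ms_res) / (nlevels(cond) * k)),
    sigma2_residual = ms_res,
    f_statistic = f_stat,
    df = c(df[i_c], df[i_r]),
    p_value = p,
    n_samples = nlevels(s), n_conditions = nlevels(cond),
    replicates_per_cell = k),
    class = "effect_fit")
}

#' @export
print.effect_fit <- function(x, ...) {
  cat(sprintf(
    "effect_fit: F(%d, %d) = %.4g, p = %s\n", x$df[1], x$df[2],
    x$f_statistic,
    if (is.na(x$p_value)) "undefined (zero residual)" else format.pval(x$p_value)))
  invisible(x)
}

# Core method-of-moments decomposition from cell summaries.
# cell: a x b matrix of sample-by-run cell means; ss_err: within-cell SS
# summed over all cells; n: replicates per cell.
vc_from_cells <- function(cell, ss_err, n) {
  a <- nrow(cell); b <- ncol(cell)
  grand <- mean(cell)
  run_mean <- colMeans(cell)
  samp_mean <- rowMeans(cell)
  ms_run <- if (b > 1) a * n * sum((run_mean - grand)^2) / (b - 1) else NA_real_
  resid_cell <- cell - outer(samp_mean, rep(1, b)) -
    matrix(run_mean, a, b, byrow = TRUE) + grand
  ms_int <- if (a > 1 && b > 1) {
    n * sum(resid_cell^2) / ((a - 1) * (b - 1))
  } else {
    NA_real_
  }
  ms_err <- if (n > 1) ss_err / (a * b * (n - 1)) else NA_real_
  s2_res <- ms_err
  s2_int <- if (!is.na(ms_int) && !is.na(ms_err)) {
    max(0, (ms_int - ms_err) / n)
  } else {
    NA_real_
  }
  s2_run <- if (!is.na(ms_run) && !is.na(ms_int)) {
    max(0, (ms_run - ms_int) / (a * n))
  } else {
    NA_real_
  }
  list(sigma2_run = s2_run, sigma2_interaction = s2_int,
       sigma2_residual = s2_res)
}

# Per-sample cell summaries for a balanced sample x run table; used by the
# estimator and by the block bootstrap.
vc_summaries <- function(tab) {
  need <- c("sample_id", "run_id", "score")
  miss <- setdiff(need, names(tab))
  if (length(miss)) abort("score table lacks columns: %s",
                          paste(miss, collapse = ", "))
  for (col in c("lab_id", "condition")) {
    if (col %in% names(tab) && length(unique(tab[[col]])) > 1L) {
      abort("`%s` has several levels; variance components expect a single %s (subset first)",
            col, sub("_id", "", col))
    }
  }
  s <- factor(tab$sample_id)
  r <- factor(tab$run_id)
  cells <- table(s, r)
  if (length(unique(as.vector(cells))) != 1L || any(cells == 0)) {
    abort("unbalanced design: every sample x run cell needs the same replicate count")
  }
  n <- unique(as.vector(cells))
  cell <- tapply(tab$score, list(s, r), mean)
  fitted <- cell[cbind(as.integer(s), as.integer(r))]
  err <- tab$score - fitted
  # within-cell error SS per sample (rows of `cell`)
  ss_by_sample <- tapply(err^2, s, sum)
  list(cell = cell, ss_by_sample = as.numeric(ss_by_sample), n = n,
       a = nlevels(s), b = nlevels(r), samples = levels(s))
}

#' Variance components of assay reproducibility
#'
#' ANOVA (method-of-moments) decomposition of replicate-level classifier
#' scores from a balanced crossed design — every sample tested with the same
#' number of replicates in every run — under the model
#' `score = sample + run + sample:run + residual` with the run and
#' interaction effects random. Expected mean squares give
#' `sigma2_residual = MS_err`, `sigma2_interaction = (MS_int - MS_err)/n`,
#' `sigma2_run = (MS_run - MS_int)/(a n)`; negative solutions are truncated
#' to zero. Derived summaries: the pooled intra-run SD
#' `sqrt(sigma2_residual)` (variability of technical replication) and the
#' pooled inter-run SD `sqrt(sigma2_run + sigma2_interaction +
#' sigma2_residual)` (total experimental variability other than
#' sample-specific effects). A single run or a single replicate leaves the
#' inestimable components `NA`, not zero.
#'
#' @param tab a score table with `sample_id`, `run_id`, `replicate_id`,
#'   `score`; a single lab and condition.
#' @return object of class `variance_components` with `sigma2_run`,
#'   `sigma2_interaction`, `sigma2_residual`, `intra_run_sd`,
#'   `inter_run_sd`, and the design `(n_samples, n_runs, n_replicates)`.
#' @export
estimate_variance_components <- function(tab) {
  sm <- vc_summaries(tab)
  if (sm$b < 2L) {
    vc <- list(sigma2_run = NA_real_, sigma2_interaction = NA_real_,
               sigma2_residual = if (sm$n > 1) {
                 sum(sm$ss_by_sample) / (sm$a * sm$b * (sm$n - 1))
               } else NA_real_)
  } else {
    vc <- vc_from_cells(sm$cell, sum(sm$ss_by_sample), sm$n)
  }
  intra <- sqrt(vc$sigma2_residual)
  inter <- sqrt(vc$sigma2_run + vc$sigma2_interaction + vc$sigma2_residual)
  structure(c(vc, list(intra_run_sd = intra, inter_run_sd = inter,
                       design = c(n_samples = sm$a, n_runs = sm$b,
                                  n_replicates = sm$n))),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat("variance_components (sample x run, balanced)\n")
  cat(sprintf("  sigma^2 run         %s\n", format(x$sigma2_run)))
  cat(sprintf("  sigma^2 interaction %s\n", format(x$sigma2_interaction)))
  cat(sprintf("  sigma^2 residual    %s\n", format(x$sigma2_residual)))
  cat(sprintf("  intra-run SD %s   inter-run SD %s\n",
              format(x$intra_run_sd), format(x$inter_run_sd)))
  invisible(x)
}

#' Pooled standard deviation of replicate groups
#'
#' Square root of the degrees-of-freedom-weighted mean of within-group
#' variances. Groups with fewer than two members contribute nothing; if all
#' groups are singletons the pooled SD is undefined (`NA`).
#'
#' @param x a list of numeric vectors (one per group), or a numeric vector
#'   accompanied by `g`.
#' @param g optional grouping vector aligned with `x`.
#' @return single numeric pooled SD, or `NA_real_`.
#' @export
pooled_sd <- function(x, g = NULL) {
  groups <- if (is.list(x)) x else split(as.numeric(x), g)
  ns <- lengths(groups)
  keep <- ns >= 2L
  if (!any(keep)) return(NA_real_)
  vars <- vapply(groups[keep], stats::var, numeric(1))
  df <- ns[keep] - 1L
  sqrt(sum(df * vars) / sum(df))
}

#' Inter-class (biological) score SD
#'
#' The biological spread of the score distribution: the SD of per-sample
#' mean scores, pooled over both classes — i.e. replicate scores are first
#' averaged within each sample, and a single SD is taken across all samples
#' of both classes. This is the statistic reported as "inter-class SD" in
#' reproducibility summaries; technical replication averages out of it,
#' class separation and within-class biological spread remain.
#'
#' @param tab a score table with `sample_id` and `score` (replicates
#'   allowed).
#' @return single numeric SD.
#' @export
inter_class_sd <- function(tab) {
  if (!all(c("sample_id", "score") %in% names(tab))) {
    abort("score table lacks sample_id/score")
  }
  means <- tapply(tab$score, tab$sample_id, mean)
  if (length(means) < 2L) abort("need >= 2 samples")
  stats::sd(means)
}

#' Block-bootstrap confidence interval for a reproducibility SD
#'
#' Resamples whole samples (with their complete replicate structure) with
#' replacement — replicates within a sample are dependent, so the sample is
#' the exchangeable unit — recomputes the statistic on each resample, and
#' returns the percentile interval. A resample on which the statistic is
#' undefined is redrawn and counted.
#'
#' @param tab a balanced score table (see
#'   [estimate_variance_components()]).
#' @param statistic `"intra_run_sd"` or `"inter_run_sd"` (fast paths), or a
#'   function `tab -> scalar`.
#' @param B number of bootstrap resamples, `>= 200`.
#' @param seed integer seed; identical seeds give identical intervals.
#' @param level confidence level (default 0.95).
#' @return list with `estimate` (statistic on the original table), `ci`
#'   (two-sided percentile interval), `B`, `n_redraws`, and the bootstrap
#'   replicates `boot`.
#' @export
bootstrap_sd_ci <- function(tab, statistic = "intra_run_sd", B = 2000,
                            seed = 1L, level = 0.95) {
  B <- check_count(B, "B", min = 200L)
  ids <- unique(tab$sample_id)
  a <- length(ids)
  if (a < 3L) abort("bootstrap needs >= 3 distinct samples")
  alpha <- (1 - level) / 2
  fast <- is.character(statistic) &&
    statistic %in% c("intra_run_sd", "inter_run_sd")
  if (fast) {
    sm <- vc_summaries(tab)
    est_obj <- estimate_variance_components(tab)
    estimate <- est_obj[[statistic]]
    one <- function(idx) {
      if (statistic == "intra_run_sd") {
        sqrt(sum(sm$ss_by_sample[idx]) / (a * sm$b * (sm$n - 1)))
      } else {
        vc <- vc_from_cells(sm$cell[idx, , drop = FALSE],
                            sum(sm$ss_by_sample[idx]), sm$n)
        sqrt(vc$sigma2_run + vc$sigma2_interaction + vc$sigma2_residual)
      }
    }
  } else if (is.function(statistic)) {
    estimate <- statistic(tab)
    rows_by_id <- split(seq_len(nrow(tab)), tab$sample_id)[ids]
    one <- function(idx) {
      rows <- rows_by_id[idx]
      tb <- tab[unlist(rows), , drop = FALSE]
      # relabel so a sample drawn twice acts as two distinct blocks
      tb$sample_id <- rep(paste0(ids[idx], "#", seq_along(idx)),
                          lengths(rows))
      statistic(tb)
    }
  } else {
    abort("`statistic` must be 'intra_run_sd', 'inter_run_sd', or a function")
  }
  boot <- numeric(B)
  n_redraws <- 0L
  with_seed(seed, {
    for (i in seq_len(B)) {
      repeat {
        v <- one(sample.int(a, a, replace = TRUE))
        if (is.finite(v)) break
        n_redraws <- n_redraws + 1L
        if (n_redraws > 100L * B) abort("statistic undefined on too many resamples")
      }
      boot[i] <- v
    }
  })
  list(estimate = estimate,
       ci = unname(stats::quantile(boot, c(alpha, 1 - alpha))),
       level = level, B = B, n_redraws = n_redraws, boot = boot)
}

#' Inter-laboratory comparison of paired classifier scores
#'
#' For a two-lab paired design (every sample scored once in each lab):
#' call concordance and Pearson r-squared, the inter-laboratory pooled SD —
#' the SD of the two lab scores of each sample, pooled across samples, equal
#' to `|difference|/sqrt(2)` per pair — with a block-bootstrap percentile
#' CI, and the fixed lab effect tested by [fit_effect_model()] with the
#' laboratory as the condition.
#'
#' @param tab a score table whose `lab_id` has exactly two levels.
#' @param threshold decision threshold for binary calls (default the table's
#'   `threshold` attribute, else 0); calls are positive strictly above it.
#' @param B,seed,level bootstrap settings for the pooled-SD CI; `B = 0`
#'   skips the CI.
#' @return object of class `interlab_result`: `n_pairs`, `n_excluded`,
#'   `concordance`, `r_squared`, `pooled_sd`, `ci`, `lab_effect`.
#' @export
interlab_analysis <- function(tab, threshold = NULL, B = 2000, seed = 1L,
                              level = 0.95) {
  need <- c("sample_id", "lab_id", "score")
  miss <- setdiff(need, names(tab))
  if (length(miss)) abort("score table lacks columns: %s",
                          paste(miss, collapse = ", "))
  labs <- sort(unique(tab$lab_id))
  if (length(labs) != 2L) {
    abort("interlab_analysis expects exactly two labs (got %d)", length(labs))
  }
  threshold <- threshold %||% attr(tab, "threshold") %||% 0
  cnt <- table(tab$sample_id, tab$lab_id)
  paired <- rownames(cnt)[cnt[, 1] == 1 & cnt[, 2] == 1]
  n_excluded <- length(unique(tab$sample_id)) - length(paired)
  if (n_excluded > 0) {
    warning(sprintf("%d sample(s) without exactly one score per lab excluded",
                    n_excluded))
  }
  if (length(paired) < 3L) abort("need >= 3 paired samples")
  sub <- tab[tab$sample_id %in% paired, , drop = FALSE]
  wide_a <- sub$score[sub$lab_id == labs[1]][order(sub$sample_id[sub$lab_id == labs[1]])]
  wide_b <- sub$score[sub$lab_id == labs[2]][order(sub$sample_id[sub$lab_id == labs[2]])]
  pcc <- paired_correlation_concordance(
    wide_a, wide_b,
    calls_a = wide_a > threshold, calls_b = wide_b > threshold)
  d2 <- (wide_a - wide_b)^2 / 2   # per-pair variance, 1 df each
  psd <- sqrt(mean(d2))
  ci <- NULL
  if (B >= 200) {
    n <- length(d2)
    alpha <- (1 - level) / 2
    boot <- with_seed(seed, vapply(seq_len(B), function(i) {
      sqrt(mean(d2[sample.int(n, n, replace = TRUE)]))
    }, numeric(1)))
    ci <- unname(stats::quantile(boot, c(alpha, 1 - alpha)))
  }
  eff <- fit_effect_model(sub, condition_col = "lab_id")
  structure(list(n_pairs = length(paired), n_excluded = n_excluded,
                 concordance = pcc$concordance, r_squared = pcc$r_squared,
                 pooled_sd = psd, ci = ci, lab_effect = eff,
                 threshold = threshold),
            class = "interlab_result")
}

#' @export
print.interlab_result <- function(x, ...) {
  cat(sprintf(
    "interlab_result: %d pairs, concordance %.3f, R^2 %.4f, pooled SD %.4g\n",
    x$n_pairs, x$concordance, x$r_squared, x$pooled_sd))
  if (!is.null(x$ci)) {
    cat(sprintf("  95%% CI [%.4g, %.4g]\n", x$ci[1], x$ci[2]))
  }
  invisible(x)
}
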