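#' Construct a count matrix with sample metadata
#'
#' A `count_matrix` bundles a nonnegative gene-by-sample expression matrix
#' with per-sample metadata. Counts are real-valued, not integer, because
#' in-silico mixtures of count profiles are convex combinations and need not
#' round to whole reads.
#'
#' @param counts numeric matrix, genes in rows, samples in columns; dimnames
#'   required and unique; all entries finite and `>= 0`.
#' @param meta data.frame with one row per sample and columns `sample_id`,
#'   `true_class` (`"positive"` or `"negative"`), `interferent_kind`
#'   (`"none"`, `"blood"`, `"gDNA"`), `interferent_fraction` in `[0, 1]`.
#'   Missing metadata columns are filled with defaults (`none`, `0`).
#' @return an object of class `count_matrix`: a list with elements `counts`
#'   and `meta`.
#' @export
count_matrix <- function(counts, meta) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    abort("`counts` must be a numeric matrix (genes x samples)")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("`counts` must carry gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(counts))) abort("gene identifiers must be unique")
  if (anyDuplicated(colnames(counts))) abort("sample identifiers must be unique")
  if (any(!is.finite(counts)) || any(counts < 0)) {
    abort("`counts` must be finite and nonnegative")
  }
  if (missing(meta) || is.null(meta)) {
    meta <- data.frame(sample_id = colnames(counts))
  }
  if (!is.data.frame(meta) || !"sample_id" %in% names(meta)) {
    abort("`meta` must be a data.frame with a `sample_id` column")
  }
  if (!setequal(meta$sample_id, colnames(counts)) ||
      nrow(meta) != ncol(counts)) {
    abort("`meta` must cover every sample exactly once")
  }
  meta <- meta[match(colnames(counts), meta$sample_id), , drop = FALSE]
  if (is.null(meta$true_class)) meta$true_class <- NA_character_
  if (is.null(meta$interferent_kind)) meta$interferent_kind <- "none"
  if (is.null(meta$interferent_fraction)) meta$interferent_fraction <- 0
  bad <- !meta$true_class %in% c("positive", "negative", NA_character_)
  if (any(bad)) abort("`true_class` must be 'positive' or 'negative'")
  if (!all(meta$interferent_kind %in% c("none", "blood", "gDNA"))) {
    abort("`interferent_kind` must be one of none, blood, gDNA")
  }
  if (any(meta$interferent_fraction < 0 | meta$interferent_fraction > 1)) {
    abort("`interferent_fraction` must lie in [0, 1]")
  }
  rownames(meta) <- NULL
  structure(list(counts = counts, meta = meta), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cls <- table(x$meta$true_class, useNA = "ifany")
  cat("  classes:", paste(names(cls), cls, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Generator truth for synthetic score tables
#'
#' Collects the ground-truth parameters of the additive score model
#' \deqn{S_{ijk} = \mu_i + r_j + (\mu_i{:}r_j) + \epsilon_{ijk}}
#' used by [gen_score_table()]: a fixed per-sample mean (class mean plus a
#' sample deviation), a random run effect, a random sample-by-run
#' interaction, and a residual. All effects are Gaussian and additive; class
#' means sit symmetric about the decision threshold (score 0).
#'
#' @param n_samples_per_class samples per class (positive and negative).
#' @param class_mean_separation distance between the two class means, in
#'   score units.
#' @param sigma_sample SD of the per-sample deviation around its class mean.
#' @param sigma_run SD of the run effect \eqn{r_j}.
#' @param sigma_interaction SD of the sample-by-run interaction.
#' @param sigma_residual SD of the replicate residual \eqn{\epsilon_{ijk}}.
#' @param score_range declared width of the classifier score scale (metadata;
#'   scores themselves are unbounded Gaussians).
#' @param seed integer seed consumed by [gen_score_table()].
#' @return an object of class `generator_truth`.
#' @export
generator_truth <- function(n_samples_per_class, class_mean_separation = 4,
                            sigma_sample = 1, sigma_run = 0,
                            sigma_interaction = 0, sigma_residual = 0,
                            score_range = 8, seed = 1L) {
  n_samples_per_class <- check_count(n_samples_per_class, "n_samples_per_class")
  sds <- c(sigma_sample = sigma_sample, sigma_run = sigma_run,
           sigma_interaction = sigma_interaction,
           sigma_residual = sigma_residual)
  if (any(!is.finite(sds)) || any(sds < 0)) {
    abort("all SDs must be finite and >= 0")
  }
  if (!is.finite(score_range) || score_range <= 0) {
    abort("`score_range` must be > 0")
  }
  structure(list(n_samples_per_class = n_samples_per_class,
                 class_mean_separation = as.numeric(class_mean_separation),
                 sigma_sample = as.numeric(sigma_sample),
                 sigma_run = as.numeric(sigma_run),
                 sigma_interaction = as.numeric(sigma_interaction),
                 sigma_residual = as.numeric(sigma_residual),
                 score_range = as.numeric(score_range),
                 seed = as.integer(seed)),
            class = "generator_truth")
}

#' Generator truth parameterized by reproducibility summaries
#'
#' Builds a [generator_truth()] from the two summaries a reproducibility
#' study reports: the pooled intra-run SD (the residual SD) and the pooled
#' inter-run SD (the square root of run + interaction + residual variance).
#' The run/interaction split is not identified by those two numbers; the
#' remaining variance is divided equally between the run effect and the
#' sample-by-run interaction.
#'
#' @param intra_run_sd pooled intra-run (residual) SD, `>= 0`.
#' @param inter_run_sd pooled inter-run SD, `>= intra_run_sd`.
#' @param n_samples_per_class,class_mean_separation,sigma_sample,score_range,seed
#'   passed to [generator_truth()].
#' @return a `generator_truth`.
#' @export
reproducibility_truth <- function(intra_run_sd, inter_run_sd,
                                  n_samples_per_class = 8,
                                  class_mean_separation = 4,
                                  sigma_sample = 1, score_range = 8,
                                  seed = 1L) {
  if (inter_run_sd < intra_run_sd) {
    abort("`inter_run_sd` must be >= `intra_run_sd`")
  }
  extra <- (inter_run_sd^2 - intra_run_sd^2) / 2
  generator_truth(n_samples_per_class = n_samples_per_class,
                  class_mean_separation = class_mean_separation,
                  sigma_sample = sigma_sample,
                  sigma_run = sqrt(extra),
                  sigma_interaction = sqrt(extra),
                  sigma_residual = intra_run_sd,
                  score_range = score_range, seed = seed)
}

#' Simulate a negative-binomial two-class count matrix
#'
#' Emulates bulk RNA-seq counts downstream of alignment and read counting:
#' per-gene baseline means are log-normal, counts are negative binomial with
#' a common dispersion, library sizes vary multiplicatively across samples,
#' and a subset of informative genes carries a class-dependent log2
#' fold change. Samples are split evenly into a classifier-positive and a
#' classifier-negative class.
#'
#' @param n_genes number of genes.
#' @param n_per_class samples per class.
#' @param n_informative number of class-informative genes
#'   (`<= n_genes`); half are up- and half down-regulated in the positive
#'   class.
#' @param effect_size absolute log2 fold change of informative genes.
#' @param dispersion negative-binomial dispersion (`size = 1/dispersion`);
#'   must be `> 0`.
#' @param libsize_cv coefficient of variation of the log-normal per-sample
#'   library-size factors.
#' @param seed integer seed; identical seeds give bit-identical matrices.
#' @return a [count_matrix()] whose `meta$true_class` records the class.
#' @export
gen_count_matrix <- function(n_genes, n_per_class, n_informative = 0,
                             effect_size = 1, dispersion = 0.1,
                             libsize_cv = 0.2, seed = 1L) {
  n_genes <- check_count(n_genes, "n_genes")
  n_per_class <- check_count(n_per_class, "n_per_class")
  n_informative <- check_count(n_informative, "n_informative", min = 0L)
  if (n_informative > n_genes) abort("`n_informative` must be <= `n_genes`")
  if (!is.finite(dispersion) || dispersion <= 0) {
    abort("`dispersion` must be > 0")
  }
  if (!is.finite(libsize_cv) || libsize_cv < 0) {
    abort("`libsize_cv` must be >= 0")
  }
  n <- 2L * n_per_class
  genes <- sprintf("g%05d", seq_len(n_genes))
  samples <- sprintf("s%04d", seq_len(n))
  class <- rep(c("positive", "negative"), each = n_per_class)
  with_seed(seed, {
    base_mu <- stats::rlnorm(n_genes, meanlog = log(50), sdlog = 1)
    # class-dependent means: informative genes shifted by +/- effect_size
    lfc <- numeric(n_genes)
    if (n_informative > 0) {
      up <- seq_len(ceiling(n_informative / 2))
      dn <- setdiff(seq_len(n_informative), up)
      lfc[up] <- effect_size
      lfc[dn] <- -effect_size
    }
    mu_pos <- base_mu * 2^lfc
    mu_neg <- base_mu
    if (libsize_cv > 0) {
      sdlog <- sqrt(log1p(libsize_cv^2))
      sf <- stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else {
      sf <- rep(1, n)
    }
    mu <- cbind(matrix(mu_pos, n_genes, n_per_class),
                matrix(mu_neg, n_genes, n_per_class))
    mu <- sweep(mu, 2, sf, "*")
    counts <- matrix(stats::rnbinom(n_genes * n, mu = mu,
                                    size = 1 / dispersion),
                     n_genes, n, dimnames = list(genes, samples))
    meta <- data.frame(sample_id = samples, true_class = class,
                       interferent_kind = "none", interferent_fraction = 0,
                       stringsAsFactors = FALSE)
    attr_truth <- list(informative = genes[seq_len(n_informative)],
                       effect_size = effect_size, libsize = sf,
                       mu_pos = mu_pos, mu_neg = mu_neg)
    out <- count_matrix(counts, meta)
    attr(out, "truth") <- attr_truth
    out
  })
}

#' Simulate replicate-level classifier scores under the additive run model
#'
#' Draws a fully crossed, balanced score table: every sample is scored in
#' every run, replicate, lab and condition. Scores follow
#' `class mean + sample deviation + run effect + sample:run interaction +
#' condition effect + residual`, each Gaussian with the SDs in `truth`.
#' Run and interaction effects are shared across labs and conditions; labs
#' and conditions differ only through their own effects and residual draws.
#'
#' @param truth a [generator_truth()].
#' @param n_runs,n_reps,n_labs design dimensions, each `>= 1`.
#' @param conditions character vector of condition labels (default a single
#'   `"std"` condition).
#' @param condition_effects numeric fixed effect added per condition
#'   (default all zero); same length as `conditions`.
#' @param drop_qc_failure drop one record at random, mimicking a single
#'   assay lost to QC; the result is then unbalanced.
#' @return a `score_table` data.frame with columns `sample_id`, `true_class`,
#'   `condition`, `run_id`, `lab_id`, `replicate_id`, `score`, and attributes
#'   `truth` and `threshold` (0; class means sit at +/- separation/2).
#' @export
gen_score_table <- function(truth, n_runs = 1, n_reps = 1, n_labs = 1,
                            conditions = "std", condition_effects = NULL,
                            drop_qc_failure = FALSE) {
  if (!inherits(truth, "generator_truth")) {
    abort("`truth` must be a generator_truth object")
  }
  n_runs <- check_count(n_runs, "n_runs")
  n_reps <- check_count(n_reps, "n_reps")
  n_labs <- check_count(n_labs, "n_labs")
  if (is.null(condition_effects)) condition_effects <- numeric(length(conditions))
  if (length(condition_effects) != length(conditions)) {
    abort("`condition_effects` must match `conditions` in length")
  }
  npc <- truth$n_samples_per_class
  n_samp <- 2L * npc
  ids <- sprintf("S%03d", seq_len(n_samp))
  class <- rep(c("positive", "negative"), each = npc)
  class_mean <- ifelse(class == "positive", 1, -1) *
    truth$class_mean_separation / 2
  with_seed(truth$seed, {
    mu <- class_mean + stats::rnorm(n_samp, 0, truth$sigma_sample)
    r <- stats::rnorm(n_runs, 0, truth$sigma_run)
    inter <- matrix(stats::rnorm(n_samp * n_runs, 0, truth$sigma_interaction),
                    n_samp, n_runs)
    grid <- expand.grid(replicate_id = seq_len(n_reps),
                        run = seq_len(n_runs),
                        sample = seq_len(n_samp),
                        lab = seq_len(n_labs),
                        cond = seq_along(conditions),
                        KEEP.OUT.ATTRS = FALSE)
    eps <- stats::rnorm(nrow(grid), 0, truth$sigma_residual)
    score <- mu[grid$sample] + r[grid$run] +
      inter[cbind(grid$sample, grid$run)] +
      condition_effects[grid$cond] + eps
    tab <- data.frame(sample_id = ids[grid$sample],
                      true_class = class[grid$sample],
                      condition = conditions[grid$cond],
                      run_id = sprintf("R%02d", grid$run),
                      lab_id = sprintf("L%02d", grid$lab),
                      replicate_id = grid$replicate_id,
                      score = score,
                      stringsAsFactors = FALSE)
    if (isTRUE(drop_qc_failure)) tab <- tab[-sample.int(nrow(tab), 1L), ]
    rownames(tab) <- NULL
    class(tab) <- c("score_table", "data.frame")
    attr(tab, "truth") <- truth
    attr(tab, "threshold") <- 0
    tab
  })
}

#' Simulate an interferent RNA expression profile
#'
#' Blood contamination concentrates sequencing reads in a small set of
#' blood marker genes (hemoglobin-like dominance); genomic DNA carryover
#' instead adds a near-uniform low-level background across all genes, since
#' gDNA reads are not shaped by transcriptional regulation.
#'
#' @param kind `"blood"` or `"gDNA"`.
#' @param n_genes number of genes; gene names match [gen_count_matrix()].
#' @param seed integer seed.
#' @param marker_fraction fraction of genes designated blood markers
#'   (default 0.05, at least 1 gene).
#' @param concentration fraction of total blood counts carried by the marker
#'   subset (default 0.9).
#' @return a named nonnegative count vector of length `n_genes`, with
#'   attribute `markers` naming the blood marker genes (blood only).
#' @export
gen_interference_profile <- function(kind, n_genes, seed = 1L,
                                     marker_fraction = 0.05,
                                     concentration = 0.9) {
  if (!is.character(kind) || length(kind) != 1L ||
      !kind %in% c("blood", "gDNA")) {
    abort("`kind` must be 'blood' or 'gDNA'")
  }
  n_genes <- check_count(n_genes, "n_genes")
  genes <- sprintf("g%05d", seq_len(n_genes))
  total <- 1e6
  with_seed(seed, {
    if (kind == "gDNA") {
      # flat background: Poisson around a common level, small CV
      prof <- stats::rpois(n_genes, lambda = total / n_genes)
      prof <- as.numeric(prof)
      names(prof) <- genes
      prof
    } else {
      n_mark <- max(1L, round(marker_fraction * n_genes))
      markers <- sample.int(n_genes, n_mark)
      w <- stats::rgamma(n_genes, shape = 0.5, rate = 1) + 1e-6
      w_m <- stats::rgamma(n_mark, shape = 2, rate = 1) + 1e-6
      prof <- w / sum(w) * (1 - concentration) * total
      prof[markers] <- w_m / sum(w_m) * concentration * total
      names(prof) <- genes
      attr(prof, "markers") <- genes[sort(markers)]
      prof
    }
  })
}

#' Validate a score table's contract
#'
#' Checks the long-format score-table invariants: required columns present,
#' scores finite, one true class per sample, and replicate keys jointly
#' unique.
#'
#' @param tab data.frame of replicate-level scores.
#' @return `tab`, invisibly, with class `score_table` prepended.
#' @export
as_score_table <- function(tab) {
  need <- c("sample_id", "true_class", "condition", "run_id", "lab_id",
            "replicate_id", "score")
  miss <- setdiff(need, names(tab))
  if (length(miss)) abort("score table lacks columns: %s",
                          paste(miss, collapse = ", "))
  if (any(!is.finite(tab$score))) abort("scores must be finite")
  cls <- unique(tab[c("sample_id", "true_class")])
  if (anyDuplicated(cls$sample_id)) {
    abort("every sample_id must have a single true_class")
  }
  key <- tab[c("sample_id", "condition", "run_id", "lab_id", "replicate_id")]
  if (anyDuplicated(key)) {
    abort("(sample, condition, run, lab, replicate) keys must be unique")
  }
  if (!inherits(tab, "score_table")) {
    class(tab) <- c("score_table", class(tab))
  }
  invisible(tab)
}
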