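#' Default noise-SD grid for the acceptance-specification simulation
#'
#' Spans 0.36 to 2.10 in increments of 0.02 (88 settings).
#'
#' @return numeric vector of noise SDs.
#' @export
default_sigma_grid <- function() seq(0.36, 2.10, by = 0.02)

#' Noise-injection simulation over a grid of score SDs
#'
#' The 3-step tolerable-variability simulation: (1) for each grid SD
#' `sigma`, draw i.i.d. Gaussian noise `N(0, sigma^2)` and add it to every
#' original classifier score; (2) recompute binary calls at the decision
#' threshold and the performance metrics; (3) repeat `reps` times and take
#' the per-sigma median of each metric. Noise is added to scores only
#' (post-classifier), never to counts. The random stream is re-seeded per
#' sigma from `seed`, so any sub-grid reproduces the full grid's values.
#'
#' @param scores numeric classifier scores of the evaluation set.
#' @param truth_labels true classes (`"positive"`/`"negative"` or logical).
#' @param threshold decision threshold; calls are positive strictly above.
#' @param grid strictly increasing positive noise SDs (default
#'   [default_sigma_grid()]).
#' @param reps noise replicates per grid SD (default 1000).
#' @param prevalence prevalence used for PPV/NPV (default: the sample
#'   composition `mean(positive)`).
#' @param seed integer seed.
#' @return object of class `noise_tolerance`: `medians` (data.frame with
#'   `sigma` and median `sensitivity`, `specificity`, `ppv`, `npv`, plus
#'   `ppa`/`npa` aliases), and the simulation settings.
#' @export
simulate_noise_grid <- function(scores, truth_labels, threshold = 0,
                                grid = default_sigma_grid(), reps = 1000,
                                prevalence = NULL, seed = 1L) {
  pos <- as_positive(truth_labels)
  if (length(pos) != length(scores)) abort("labels must match scores")
  if (!any(pos) || all(pos)) abort("both classes must be present")
  if (!length(grid) || any(!is.finite(grid)) || any(grid <= 0)) {
    abort("`grid` must be nonempty and positive")
  }
  if (is.unsorted(grid, strictly = TRUE)) {
    abort("`grid` must be strictly increasing")
  }
  reps <- check_count(reps, "reps")
  prevalence <- prevalence %||% mean(pos)
  n <- length(scores)
  n_pos <- sum(pos); n_neg <- n - n_pos
  med <- matrix(NA_real_, length(grid), 4,
                dimnames = list(NULL, c("sensitivity", "specificity",
                                        "ppv", "npv")))
  for (i in seq_along(grid)) {
    sg <- grid[i]
    res <- with_seed(seed + i, {
      noise <- matrix(stats::rnorm(reps * n, 0, sg), reps, n)
      noisy <- sweep(noise, 2, scores, "+")
      callp <- noisy > threshold
      sens <- rowSums(callp[, pos, drop = FALSE]) / n_pos
      spec <- rowSums(!callp[, !pos, drop = FALSE]) / n_neg
      ppv_d <- sens * prevalence + (1 - spec) * (1 - prevalence)
      npv_d <- spec * (1 - prevalence) + (1 - sens) * prevalence
      cbind(sens = sens, spec = spec,
            ppv = ifelse(ppv_d > 0, sens * prevalence / ppv_d, NA_real_),
            npv = ifelse(npv_d > 0, spec * (1 - prevalence) / npv_d,
                         NA_real_))
    })
    med[i, ] <- apply(res, 2, stats::median, na.rm = TRUE)
  }
  medians <- data.frame(sigma = grid, med,
                        ppa = med[, "sensitivity"], npa = med[, "specificity"])
  structure(list(medians = medians, reps = reps, threshold = threshold,
                 prevalence = prevalence, seed = as.integer(seed),
                 n_scores = n),
            class = "noise_tolerance")
}

#' @export
print.noise_tolerance <- function(x, ...) {
  cat(sprintf(
    "noise_tolerance: %d sigma settings (%.2f-%.2f), %d reps, prevalence %.3f\n",
    nrow(x$medians), min(x$medians$sigma), max(x$medians$sigma), x$reps,
    x$prevalence))
  invisible(x)
}

#' Determine the tolerable-SD acceptance specification
#'
#' The SD specification is the largest grid noise SD at which every required
#' metric's median meets its minimum — the maximum score variability the
#' classifier tolerates while median performance still satisfies the
#' pre-specified product requirements (e.g. sensitivity >= 0.90 and
#' NPV >= 0.90). By default the largest qualifying SD is taken even if some
#' smaller SD fails by simulation noise; `monotone = TRUE` instead stops at
#' the first failure from the low end.
#'
#' @param r a `noise_tolerance` result with medians for every grid SD.
#' @param requirements named numeric vector of metric minima; names must be
#'   computed metrics (`sensitivity`, `specificity`, `ppv`, `npv`, `ppa`,
#'   `npa`).
#' @param monotone restrict to the contiguous qualifying prefix of the grid.
#' @return list with `sd_spec` (grid value, or `NA`), `status`
#'   (`"ok"` or `"below grid minimum"`), `requirements`, and the per-sigma
#'   qualification flags `qualifies`.
#' @export
determine_sd_spec <- function(r, requirements = c(sensitivity = 0.90,
                                                  npv = 0.90),
                              monotone = FALSE) {
  stopifnot(inherits(r, "noise_tolerance"))
  if (is.null(names(requirements)) || any(names(requirements) == "")) {
    abort("`requirements` must be a named numeric vector")
  }
  unknown <- setdiff(names(requirements), names(r$medians))
  if (length(unknown)) {
    abort("requirement(s) not among computed metrics: %s",
          paste(unknown, collapse = ", "))
  }
  m <- r$medians
  if (anyNA(m[names(requirements)])) {
    abort("medians undefined for some grid SDs; cannot determine the spec")
  }
  ok <- rep(TRUE, nrow(m))
  for (nm in names(requirements)) ok <- ok & m[[nm]] >= requirements[[nm]]
  if (monotone) ok <- cumall(ok)
  if (!any(ok)) {
    return(list(sd_spec = NA_real_, status = "below grid minimum",
                requirements = requirements, qualifies = ok))
  }
  list(sd_spec = max(m$sigma[ok]), status = "ok",
       requirements = requirements, qualifies = ok)
}
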