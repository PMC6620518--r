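#' Tabulate confusion counts from truth and calls
#'
#' @param truth true classes (`"positive"`/`"negative"` or logical).
#' @param calls test calls in the same encoding.
#' @return named integer vector `c(tp, fp, tn, fn)`.
#' @export
confusion_counts <- function(truth, calls) {
  if (length(truth) != length(calls)) abort("`truth`/`calls` lengths differ")
  tp_ <- as_positive(truth); cp <- as_positive(calls)
  c(tp = sum(tp_ & cp), fp = sum(!tp_ & cp),
    tn = sum(!tp_ & !cp), fn = sum(tp_ & !cp))
}

as_positive <- function(x) {
  if (is.logical(x)) return(x)
  x <- as.character(x)
  if (!all(x %in% c("positive", "negative"))) {
    abort("calls must be 'positive'/'negative' or logical")
  }
  x == "positive"
}

#' Diagnostic performance from confusion counts
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, and predictive
#' values. By default PPV/NPV are the count-based ratios (i.e. at the sample
#' prevalence); when `prevalence` is supplied they are recomputed by the
#' Bayes rearrangement
#' `NPV = spec (1-prev) / (spec (1-prev) + (1-sens) prev)` and analogously
#' for PPV. A metric with a zero denominator is reported as `NA`, never as
#' zero.
#'
#' @param tp,fp,tn,fn nonnegative counts; `tp` may also be the named vector
#'   from [confusion_counts()].
#' @param prevalence optional positive-class prevalence in `(0, 1)`.
#' @return named numeric `c(sensitivity, specificity, ppv, npv)`.
#' @export
confusion_metrics <- function(tp, fp = NULL, tn = NULL, fn = NULL,
                              prevalence = NULL) {
  if (is.null(fp) && length(tp) == 4L && !is.null(names(tp))) {
    fp <- tp[["fp"]]; tn <- tp[["tn"]]; fn <- tp[["fn"]]; tp <- tp[["tp"]]
  }
  cts <- c(tp, fp, tn, fn)
  if (any(cts < 0) || sum(cts) < 1) abort("counts must be nonnegative, total >= 1")
  rat <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- rat(tp, tp + fn)
  spec <- rat(tn, tn + fp)
  if (is.null(prevalence)) {
    ppv <- rat(tp, tp + fp)
    npv <- rat(tn, tn + fn)
  } else {
    prevalence <- check_fraction(prevalence, "prevalence")
    ppv <- if (is.na(sens) || is.na(spec)) NA_real_ else {
      d <- sens * prevalence + (1 - spec) * (1 - prevalence)
      if (d > 0) sens * prevalence / d else NA_real_
    }
    npv <- if (is.na(sens) || is.na(spec)) NA_real_ else {
      d <- spec * (1 - prevalence) + (1 - sens) * prevalence
      if (d > 0) spec * (1 - prevalence) / d else NA_real_
    }
  }
  c(sensitivity = sens, specificity = spec, ppv = ppv, npv = npv)
}

#' Positive and negative percent agreement against a reference method
#'
#' PPA is the fraction of reference-positive samples the test also calls
#' positive; NPA the fraction of reference-negatives called negative.
#' An empty reference stratum leaves the corresponding metric `NA`.
#'
#' @param ref_calls reference-method calls.
#' @param test_calls test calls, same length and encoding.
#' @return list with `ppa`, `npa` (proportions or `NA`) and the
#'   numerator/denominator counts.
#' @export
ppa_npa <- function(ref_calls, test_calls) {
  if (length(ref_calls) != length(test_calls)) abort("lengths differ")
  rp <- as_positive(ref_calls); tp_ <- as_positive(test_calls)
  n_rp <- sum(rp); n_rn <- sum(!rp)
  list(ppa = if (n_rp > 0) sum(tp_[rp]) / n_rp else NA_real_,
       npa = if (n_rn > 0) sum(!tp_[!rp]) / n_rn else NA_real_,
       ppa_num = sum(tp_[rp]), ppa_den = n_rp,
       npa_num = sum(!tp_[!rp]), npa_den = n_rn)
}

#' Variant call from a variant allele frequency
#'
#' Positive iff `vaf >= threshold` — the threshold itself is called
#' positive (inclusive rule); anything below is wild type.
#'
#' @param vaf variant allele frequency/frequencies in `[0, 1]`.
#' @param threshold call threshold (default 0.05).
#' @return character vector, `"positive"` or `"wild-type"`.
#' @export
vaf_call <- function(vaf, threshold = 0.05) {
  if (any(!is.finite(vaf)) || any(vaf < 0) || any(vaf > 1)) {
    abort("`vaf` must lie in [0, 1]")
  }
  threshold <- check_fraction(threshold, "threshold")
  ifelse(vaf >= threshold, "positive", "wild-type")
}

#' Paired score correlation and call concordance
#'
#' Pearson correlation (and its square) between paired score vectors — the
#' inter-laboratory comparison statistic — plus the fraction of matching
#' binary calls when calls are supplied. Zero variance in either score
#' vector leaves the correlation `NA`.
#'
#' @param scores_a,scores_b paired scores, length `>= 3`.
#' @param calls_a,calls_b optional paired calls.
#' @return list with `r`, `r_squared`, `concordance` (`NA` when no calls
#'   given), `n`.
#' @export
paired_correlation_concordance <- function(scores_a, scores_b,
                                           calls_a = NULL, calls_b = NULL) {
  if (length(scores_a) != length(scores_b)) abort("score lengths differ")
  if (length(scores_a) < 3L) abort("correlation needs >= 3 pairs")
  r <- if (stats::sd(scores_a) == 0 || stats::sd(scores_b) == 0) {
    NA_real_
  } else {
    stats::cor(scores_a, scores_b)
  }
  conc <- NA_real_
  if (!is.null(calls_a) && !is.null(calls_b)) {
    if (length(calls_a) != length(calls_b)) abort("call lengths differ")
    conc <- mean(as_positive(calls_a) == as_positive(calls_b))
  }
  list(r = r, r_squared = r^2, concordance = conc, n = length(scores_a))
}
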