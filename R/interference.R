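#' Contaminate a specimen profile with an interferent
#'
#' Convex combination of an interferent profile (blood-derived RNA or a
#' gDNA-like flat background) into a specimen count profile at a given mass
#' fraction, after equal-total rescaling — the same contract as
#' [mix_counts()] with the interferent as the `p`-weighted component.
#'
#' @param sample named count vector of the specimen.
#' @param interferent named count vector over the same genes.
#' @param fraction interferent mass fraction in `[0, 1]`.
#' @param rescale passed to [mix_counts()].
#' @return contaminated count vector.
#' @export
make_contaminated <- function(sample, interferent, fraction, rescale = TRUE) {
  mix_counts(interferent, sample, fraction, rescale = rescale)
}

#' Fit a four-parameter logistic to score-vs-fraction titration data
#'
#' Least-squares 4PL fit
#' `y = lower + (upper - lower) / (1 + exp(-slope * (x - inflection)))`
#' in the fraction domain, used to interpolate classifier scores across an
#' interferent titration. Fitting is attempted with a self-starting
#' logistic ([stats::SSfpl]), falling back to Levenberg-Marquardt
#' ([minpack.lm::nlsLM]); if neither converges (e.g. perfectly flat scores)
#' a constant fit is returned with `degenerate = TRUE`.
#'
#' @param fractions numeric vector in `[0, 1]`, at least 4 distinct values.
#' @param scores numeric vector of classifier scores.
#' @param threshold optional decision threshold; when supplied and strictly
#'   between the asymptotes, the fraction at which the fitted curve crosses
#'   it is reported (only if it lies in `[0, 1]`).
#' @return object of class `sigmoid_fit`: `lower`, `upper`, `inflection`,
#'   `slope` (signed; negative for decreasing curves), `rss`, `crossing`
#'   (may be `NA`), `degenerate`, and `predict(fit)(x)`.
#' @export
fit_sigmoid <- function(fractions, scores, threshold = NULL) {
  if (length(fractions) != length(scores)) abort("input lengths differ")
  if (length(unique(fractions)) < 4L) {
    abort("at least 4 distinct fractions are required for a 4PL fit")
  }
  if (any(!is.finite(fractions)) || any(!is.finite(scores))) {
    abort("inputs must be finite")
  }
  dat <- data.frame(x = as.numeric(fractions), y = as.numeric(scores))
  fit <- NULL
  if (stats::sd(dat$y) > 1e-12) {
    fit <- tryCatch(
      stats::nls(y ~ SSfpl(x, A, B, xmid, scal), data = dat),
      error = function(e) NULL)
    if (is.null(fit)) {
      up <- stats::cor(dat$x, dat$y) >= 0
      start <- list(A = if (up) min(dat$y) else max(dat$y),
                    B = if (up) max(dat$y) else min(dat$y),
                    xmid = stats::median(dat$x),
                    scal = if (up) 0.2 else -0.2)
      fit <- tryCatch(
        minpack.lm::nlsLM(y ~ A + (B - A) / (1 + exp((xmid - x) / scal)),
                          data = dat, start = start,
                          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
    }
  }
  if (is.null(fit)) {
    m <- mean(dat$y)
    out <- structure(list(lower = m, upper = m, inflection = NA_real_,
                          slope = 0, rss = sum((dat$y - m)^2),
                          crossing = NA_real_, degenerate = TRUE),
                     class = "sigmoid_fit")
    return(out)
  }
  cf <- stats::coef(fit)  # A = left asymptote, B = right, xmid, scal
  A <- cf[["A"]]; B <- cf[["B"]]; xmid <- cf[["xmid"]]; scal <- cf[["scal"]]
  # reparametrize so lower <= upper; slope sign carries the direction
  increasing <- (B >= A) == (scal >= 0)
  lower <- min(A, B); upper <- max(A, B)
  slope <- abs(1 / scal) * (if (increasing) 1 else -1)
  crossing <- NA_real_
  if (!is.null(threshold) && upper > lower &&
      threshold > lower && threshold < upper) {
    # invert: t = A + (B-A)/(1+exp((xmid-x)/scal))
    x_t <- xmid - scal * log((B - A) / (threshold - A) - 1)
    if (is.finite(x_t) && x_t >= 0 && x_t <= 1) crossing <- x_t
  }
  structure(list(lower = lower, upper = upper, inflection = xmid,
                 slope = slope,
                 rss = sum(stats::residuals(fit)^2),
                 crossing = crossing, degenerate = FALSE,
                 coef = c(A = A, B = B, xmid = xmid, scal = scal)),
            class = "sigmoid_fit")
}

#' @export
predict.sigmoid_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.data.frame(newdata)) newdata$x else newdata
  if (is.null(x)) abort("supply fractions to predict at")
  if (object$degenerate) return(rep(object$lower, length(x)))
  cf <- object$coef
  cf[["A"]] + (cf[["B"]] - cf[["A"]]) /
    (1 + exp((cf[["xmid"]] - x) / cf[["scal"]]))
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("sigmoid_fit (degenerate constant): level %.4g\n", x$lower))
  } else {
    cat(sprintf(
      "sigmoid_fit: lower %.4g, upper %.4g, inflection %.4g, slope %.4g\n",
      x$lower, x$upper, x$inflection, x$slope))
    if (!is.na(x$crossing)) {
      cat(sprintf("  threshold crossing at fraction %.4g\n", x$crossing))
    }
  }
  invisible(x)
}

#' Maximum tolerated interference level
#'
#' Scans an ascending ladder of interference percentages and returns the
#' largest level at which the classifier call is still correct at that
#' level and at every smaller one (contiguity). For a specimen whose
#' expected class is positive the 100% point — pure interferent with no
#' specimen signal left — is not an eligible level; for an expected-negative
#' specimen all levels including 100% are eligible.
#'
#' @param levels interference percentages in `[0, 100]`, including 0.
#' @param calls calls at each level (`"positive"`/`"negative"` or logical
#'   positive-call).
#' @param expected_class expected call, `"positive"` or `"negative"`.
#' @return list with `max_level` (`NA` when the uncontaminated baseline
#'   already fails) and `baseline_pass`.
#' @export
max_tolerated_level <- function(levels, calls, expected_class = "positive") {
  if (length(levels) != length(calls)) abort("`levels`/`calls` lengths differ")
  if (!0 %in% levels) abort("`levels` must include the 0%% baseline")
  if (any(levels < 0 | levels > 100)) abort("`levels` must be percentages")
  if (is.logical(calls)) calls <- ifelse(calls, "positive", "negative")
  o <- order(levels)
  levels <- levels[o]; calls <- calls[o]
  eligible <- if (expected_class == "positive") levels < 100 else rep(TRUE, length(levels))
  correct <- calls == expected_class
  baseline_pass <- correct[levels == 0]
  if (!baseline_pass) {
    return(list(max_level = NA_real_, baseline_pass = FALSE))
  }
  ok <- cumall(correct) & eligible
  list(max_level = max(levels[ok]), baseline_pass = TRUE)
}
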