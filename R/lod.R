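#' Mix two count profiles at a mass fraction
#'
#' Per-gene convex combination `p * c1 + (1 - p) * c2`, kept real-valued
#' (no rounding). With `rescale = TRUE` (default) both parents are first
#' rescaled to their common mean total so that `p` is interpretable as an
#' RNA mass fraction rather than a sequencing-depth fraction. The endpoints
#' are exact: `p = 1` returns `c1` and `p = 0` returns `c2` unchanged —
#' a pure specimen is itself under any depth convention; rescaling only
#' defines the interpolation path at interior fractions.
#'
#' @param c1,c2 named nonnegative count vectors over the same genes
#'   (`c1` the classifier-positive parent by convention).
#' @param p mixing fraction of `c1`, in `[0, 1]`.
#' @param rescale rescale parents to a common total first.
#' @return mixed count vector over the same genes.
#' @export
mix_counts <- function(c1, c2, p, rescale = TRUE) {
  p <- check_fraction(p, "p")
  if (length(c1) != length(c2)) abort("gene sets differ in length")
  if (!is.null(names(c1)) || !is.null(names(c2))) {
    if (is.null(names(c1)) || is.null(names(c2)) ||
        !identical(names(c1), names(c2))) {
      abort("gene lists of the two parents do not match")
    }
  }
  if (p == 1) return(c1)
  if (p == 0) return(c2)
  if (rescale) {
    t1 <- sum(c1); t2 <- sum(c2)
    if (t1 <= 0 || t2 <= 0) abort("parent totals must be positive to rescale")
    tt <- (t1 + t2) / 2
    c1 <- c1 * (tt / t1)
    c2 <- c2 * (tt / t2)
  }
  p * c1 + (1 - p) * c2
}

#' In-silico titration of a positive sample into a negative background
#'
#' Builds the fine mixture grid `p = 0, grid_step, ..., 1` between a
#' classifier-positive and a classifier-negative count profile, normalizes,
#' scores each mixture with the supplied model, and determines the in-silico
#' limit of detection: the smallest grid fraction that is called positive
#' and stays positive at every larger fraction (contiguity guards against
#' non-monotone call sequences). Size factors are recomputed over the whole
#' mixture series plus the two raw parents — normalization is local to the
#' series, not inherited from any larger cohort, and the choice is recorded
#' in the result.
#'
#' @param pos,neg named count vectors: the pure classifier-positive and
#'   classifier-negative parents.
#' @param model a `linear_classifier`.
#' @param grid_step grid increment; must divide 1 evenly (default 0.01).
#' @param normalize normalize mixtures (median-of-ratios + log2) before
#'   scoring; `FALSE` scores raw mixed counts, in which case a linear model
#'   makes the score exactly affine in `p`.
#' @param check_control flag the pair invalid when the pure negative
#'   (`p = 0`) scores positive.
#' @return object of class `mixture_series`: a list with `points` (data.frame
#'   `p`, `score`, `call`), `lod` (smallest reliably-positive fraction, or
#'   `NA`), `control_pass`, and `normalization` metadata.
#' @export
in_silico_titration <- function(pos, neg, model, grid_step = 0.01,
                                normalize = TRUE, check_control = TRUE) {
  stopifnot(inherits(model, "linear_classifier"))
  if (!is.finite(grid_step) || grid_step <= 0 || grid_step > 1) {
    abort("`grid_step` must be in (0, 1]")
  }
  k <- 1 / grid_step
  if (abs(k - round(k)) > 1e-8) abort("`grid_step` must divide 1 evenly")
  p_grid <- seq(0, 1, length.out = round(k) + 1)
  mixed <- vapply(p_grid, function(p) mix_counts(pos, neg, p),
                  numeric(length(pos)))
  rownames(mixed) <- names(pos)
  colnames(mixed) <- sprintf("p%03d", round(p_grid / grid_step))
  if (normalize) {
    series <- cbind(mixed, .pos_parent = pos, .neg_parent = neg)
    sf <- size_factors(series)
    norm <- normalize_counts(series, sf)
    scored <- score_samples(model, norm[, colnames(mixed), drop = FALSE])
  } else {
    scored <- score_samples(model, mixed)
  }
  points <- data.frame(p = p_grid, score = scored$score, call = scored$call,
                       stringsAsFactors = FALSE)
  control_pass <- points$call[points$p == 0] != "positive"
  lod <- NA_real_
  if (control_pass || !check_control) {
    # smallest p > 0 called positive at itself and every larger grid point
    ok <- points$p > 0 & rev(cumall(rev(points$call == "positive" |
                                          points$p == 0)))
    if (any(ok)) lod <- min(points$p[ok])
  }
  structure(list(points = points, lod = lod, control_pass = control_pass,
                 normalization = list(
                   mode = if (normalize) "series+parents" else "none",
                   grid_step = grid_step)),
            class = "mixture_series")
}

# cumulative all(): TRUE while every element so far is TRUE
cumall <- function(x) cumprod(as.logical(x)) == 1

#' @export
print.mixture_series <- function(x, ...) {
  cat(sprintf("mixture_series: %d points, LOD = %s, negative control %s\n",
              nrow(x$points),
              if (is.na(x$lod)) "not reached" else format(x$lod),
              if (x$control_pass) "passed" else "FAILED"))
  invisible(x)
}

#' @rdname count_matrix_io
#' @param series a `mixture_series`.
#' @export
write_mixture_series <- function(series, file) {
  stopifnot(inherits(series, "mixture_series"))
  utils::write.table(series$points, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Limit of detection from a discrete in-vitro dilution design
#'
#' In the wet-lab design a classifier-positive specimen is diluted by
#' negative tissue at a coarse ladder of dilution levels (percent diluent,
#' e.g. 0/40/60/80/100%). The 100% point, when present, is a pure-negative
#' control, not an LOD point. The LOD, expressed as minimum positive-content
#' percentage, is `100 - L` where `L` is the largest dilution level (below
#' 100) at which the call is correct at that level and at every smaller
#' dilution.
#'
#' @param levels dilution percentages in `[0, 100]`; must include 0.
#' @param calls classifier calls at each level: `"positive"`/`"negative"`
#'   character, or logical positive-call indicator.
#' @param expected_class class of the undiluted specimen (default
#'   `"positive"`).
#' @return list with `lod` (percent positive content, `NA` when even the
#'   undiluted point fails), `tolerated_dilution`, `control_pass` (`NA` when
#'   no 100% control is present), `baseline_pass`.
#' @export
in_vitro_lod <- function(levels, calls, expected_class = "positive") {
  if (length(levels) != length(calls)) abort("`levels`/`calls` lengths differ")
  if (!0 %in% levels) abort("`levels` must include the undiluted 0%% point")
  if (any(levels < 0 | levels > 100)) abort("`levels` must be percentages")
  if (anyDuplicated(levels)) abort("`levels` must be distinct")
  if (is.logical(calls)) calls <- ifelse(calls, "positive", "negative")
  o <- order(levels)
  levels <- levels[o]; calls <- calls[o]
  ctrl <- levels == 100
  control_pass <- if (any(ctrl)) calls[ctrl] != expected_class else NA
  lv <- levels[!ctrl]; cl <- calls[!ctrl]
  correct <- cl == expected_class
  baseline_pass <- correct[lv == 0]
  tolerated <- if (baseline_pass) max(lv[cumall(correct)]) else NA_real_
  list(lod = if (baseline_pass) 100 - tolerated else NA_real_,
       tolerated_dilution = tolerated,
       control_pass = control_pass,
       baseline_pass = baseline_pass)
}
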