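#' Train the linear surrogate classifier
#'
#' A deliberately transparent stand-in for a proprietary trained classifier:
#' a regularized class-centroid discriminant on normalized expression. The
#' weight vector is the positive-minus-negative centroid difference shrunk
#' by the ridge penalty, `w = (c_pos - c_neg) / (1 + lambda)`; the decision
#' threshold sits at the midpoint of the two class mean scores. Because the
#' score is exactly linear in the expression profile, threshold crossings of
#' convex count mixtures have closed forms — the property the titration
#' oracles rely on. This is NOT a re-implementation of any production
#' ensemble classifier; it exists so validation machinery can be exercised
#' and tested end-to-end.
#'
#' @param X numeric genes-by-samples matrix of normalized expression.
#' @param labels per-sample class labels, `"positive"` / `"negative"`.
#' @param ridge_penalty nonnegative shrinkage `lambda`.
#' @param score_range declared score-scale width stored as metadata
#'   (default: twice the training class-mean score distance).
#' @return an object of class `linear_classifier` with elements `weights`,
#'   `intercept`, `threshold`, `score_range`.
#' @export
train_classifier <- function(X, labels, ridge_penalty = 0,
                             score_range = NULL) {
  if (!is.matrix(X) || !is.numeric(X)) abort("`X` must be a numeric matrix")
  if (length(labels) != ncol(X)) abort("`labels` must match samples")
  labels <- as.character(labels)
  if (!all(labels %in% c("positive", "negative"))) {
    abort("labels must be 'positive' or 'negative'")
  }
  if (length(unique(labels)) < 2L) {
    abort("training requires both classes present")
  }
  if (!is.finite(ridge_penalty) || ridge_penalty < 0) {
    abort("`ridge_penalty` must be >= 0")
  }
  c_pos <- rowMeans(X[, labels == "positive", drop = FALSE])
  c_neg <- rowMeans(X[, labels == "negative", drop = FALSE])
  w <- (c_pos - c_neg) / (1 + ridge_penalty)
  names(w) <- rownames(X)
  m_pos <- sum(w * c_pos)
  m_neg <- sum(w * c_neg)
  threshold <- (m_pos + m_neg) / 2
  if (is.null(score_range)) score_range <- 2 * abs(m_pos - m_neg)
  structure(list(weights = w, intercept = 0, threshold = threshold,
                 score_range = score_range),
            class = "linear_classifier")
}

#' @export
print.linear_classifier <- function(x, ...) {
  cat(sprintf(
    "linear surrogate classifier: %d genes, threshold %.4g, range %.4g\n",
    length(x$weights), x$threshold, x$score_range))
  invisible(x)
}

#' Score samples and make binary calls
#'
#' Scores are `w . x + intercept`; the call is positive iff the score is
#' strictly above the threshold. A score exactly at the threshold is called
#' negative — a rule-out test should not emit a positive on a knife-edge.
#'
#' @param model a `linear_classifier`.
#' @param X numeric genes-by-samples matrix (normalized, or raw when the
#'   linear-score oracle is wanted); must contain every model gene.
#' @return data.frame with `sample_id`, `score`, `call`.
#' @export
score_samples <- function(model, X) {
  stopifnot(inherits(model, "linear_classifier"))
  if (is.null(dim(X))) X <- matrix(X, ncol = 1,
                                   dimnames = list(names(X), "x1"))
  missing <- setdiff(names(model$weights), rownames(X))
  if (length(missing)) {
    abort("matrix lacks %d model gene(s): %s", length(missing),
          paste(utils::head(missing, 5), collapse = ", "))
  }
  Xm <- X[names(model$weights), , drop = FALSE]
  s <- drop(crossprod(Xm, model$weights)) + model$intercept
  data.frame(sample_id = colnames(X) %||% paste0("x", seq_along(s)),
             score = unname(s),
             call = ifelse(s > model$threshold, "positive", "negative"),
             stringsAsFactors = FALSE)
}
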