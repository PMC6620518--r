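# Independent oracles and small fixture builders used across the suite.

# Rank-based AUC of scores for a binary truth vector (TRUE = positive).
auc_rank <- function(scores, truth) {
  r <- rank(scores)
  n_pos <- sum(truth)
  n_neg <- sum(!truth)
  (sum(r[truth]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Closed-form in-silico LOD for a linear score affine in the mixing
# fraction: scores s1 at p = 1, s2 at p = 0, decision threshold t, calls
# strictly above t. LOD is the first grid point strictly beyond the
# crossing p* = (t - s2) / (s1 - s2).
lod_closed_form <- function(s1, s2, t, step = 0.01) {
  p_star <- (t - s2) / (s1 - s2)
  grid <- seq(0, 1, by = step)
  ok <- grid > p_star & grid > 0
  if (!any(ok)) return(NA_real_)
  min(grid[ok])
}

# A tiny hand-built linear model over named genes.
toy_model <- function(weights, threshold = 0, range = 8) {
  structure(list(weights = weights, intercept = 0, threshold = threshold,
                 score_range = range),
            class = "linear_classifier")
}

# Balanced sample x run x replicate table from explicit effect draws;
# independent of gen_score_table, for estimator checks.
manual_vc_table <- function(mu, r_eff, inter, eps) {
  a <- length(mu); b <- length(r_eff); n <- dim(eps)[3]
  rows <- expand.grid(sample = seq_len(a), run = seq_len(b),
                      rep = seq_len(n))
  data.frame(sample_id = sprintf("S%02d", rows$sample),
             true_class = "positive",
             condition = "std",
             run_id = sprintf("R%02d", rows$run),
             lab_id = "L01",
             replicate_id = rows$rep,
             score = mu[rows$sample] + r_eff[rows$run] +
               inter[cbind(rows$sample, rows$run)] +
               eps[cbind(rows$sample, rows$run, rows$rep)],
             stringsAsFactors = FALSE)
}
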