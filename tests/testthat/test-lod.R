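test_that("mixing endpoints and hand arithmetic are exact", {
  c1 <- c(g1 = 10, g2 = 0, g3 = 4)
  c2 <- c(g1 = 2, g2 = 8, g3 = 4)  # equal totals (14)
  expect_identical(mix_counts(c1, c2, 1), c1)
  expect_identical(mix_counts(c1, c2, 0), c2)
  expect_equal(mix_counts(c1, c2, 0.25), c(g1 = 4, g2 = 6, g3 = 4))
})

test_that("mixing is linear with interpolated totals", {
  c1 <- c(a = 30, b = 10)   # total 40
  c2 <- c(a = 5, b = 15)    # total 20
  for (p in c(0.2, 0.5, 0.9)) {
    mixed <- mix_counts(c1, c2, p)
    # after equal-total rescaling both parents carry total 30
    expect_equal(sum(mixed), 30)
    # convexity in the rescaled parents
    expect_equal(mixed, p * c1 * (30 / 40) + (1 - p) * c2 * (30 / 20))
  }
  # unscaled form follows the raw convex combination
  expect_equal(mix_counts(c1, c2, 0.25, rescale = FALSE),
               0.25 * c1 + 0.75 * c2)
})

test_that("mismatched gene sets are rejected", {
  expect_error(mix_counts(c(a = 1, b = 2), c(a = 1, c = 2), 0.5), "gene")
  expect_error(mix_counts(c(a = 1), c(a = 1, b = 2), 0.5), "length")
  expect_error(mix_counts(c(a = 1), c(a = 2), 1.5), "p")
})

test_that("the default titration grid has 101 points with both endpoints", {
  c1 <- c(g1 = 20, g2 = 2); c2 <- c(g1 = 2, g2 = 20)
  fit <- toy_model(c(g1 = 1, g2 = -1))
  ser <- in_silico_titration(c1, c2, fit, normalize = FALSE)
  expect_identical(nrow(ser$points), 101L)
  expect_identical(range(ser$points$p), c(0, 1))
  expect_error(in_silico_titration(c1, c2, fit, grid_step = 0.03), "evenly")
})

test_that("in-silico LOD matches the closed-form crossing for linear scores", {
  fit <- toy_model(c(g1 = 1, g2 = -1), threshold = 0)
  c1 <- c(g1 = 12, g2 = 2)  # score 10
  c2 <- c(g1 = 2, g2 = 12)  # score -10, equal totals
  ser <- in_silico_titration(c1, c2, fit, normalize = FALSE)
  expect_equal(ser$lod, lod_closed_form(10, -10, 0))
  expect_equal(ser$lod, 0.51)
  expect_true(ser$control_pass)
  # asymmetric crossing strictly between grid points
  fit2 <- toy_model(c(g1 = 1, g2 = -1), threshold = 4.1)
  ser2 <- in_silico_titration(c1, c2, fit2, normalize = FALSE)
  expect_equal(ser2$lod, lod_closed_form(10, -10, 4.1))
  expect_equal(ser2$lod, 0.71)
})

test_that("a negative control scoring positive flags the pair invalid", {
  fit <- toy_model(c(g1 = 1, g2 = 0), threshold = -1)  # everything positive
  c1 <- c(g1 = 10, g2 = 4); c2 <- c(g1 = 4, g2 = 10)
  ser <- in_silico_titration(c1, c2, fit, normalize = FALSE)
  expect_false(ser$control_pass)
  expect_true(is.na(ser$lod))
  # with the check disabled the LOD is the smallest nonzero grid point
  ser2 <- in_silico_titration(c1, c2, fit, normalize = FALSE,
                              check_control = FALSE)
  expect_equal(ser2$lod, 0.01)
})

test_that("normalized titrations still recover a detectable LOD", {
  m <- gen_count_matrix(200, 20, n_informative = 60, effect_size = 2.5,
                        dispersion = 0.05, seed = 31)
  X <- normalize_counts(m$counts, size_factors(m$counts))
  fit <- train_classifier(X, m$meta$true_class)
  pair <- gen_count_matrix(200, 1, n_informative = 60, effect_size = 2.5,
                           dispersion = 0.05, seed = 32)
  pos <- pair$counts[, pair$meta$true_class == "positive"]
  neg <- pair$counts[, pair$meta$true_class == "negative"]
  ser <- in_silico_titration(pos, neg, fit)
  expect_true(ser$control_pass)
  expect_false(is.na(ser$lod))
  expect_lt(ser$lod, 1)
  # calls above the LOD are all positive (contiguity by construction)
  expect_true(all(ser$points$call[ser$points$p >= ser$lod] == "positive"))
})

test_that("in-vitro LOD follows the contiguity rule on the coarse ladder", {
  # correct at 0/40/60/80 dilution, control correct -> tolerates 80%,
  # LOD 20% positive content
  res <- in_vitro_lod(c(0, 40, 60, 80, 100),
                      c("positive", "positive", "positive", "positive",
                        "negative"))
  expect_equal(res$lod, 20)
  expect_true(res$control_pass)

  # correct only undiluted -> LOD 100%
  res2 <- in_vitro_lod(c(0, 40, 60, 80),
                       c("positive", "negative", "negative", "negative"))
  expect_equal(res2$lod, 100)

  # a gap at 60 caps the tolerated dilution at 40
  res3 <- in_vitro_lod(c(0, 40, 60, 80),
                       c("positive", "positive", "negative", "positive"))
  expect_equal(res3$lod, 60)

  # positive call on the pure-negative control is a control failure
  res4 <- in_vitro_lod(c(0, 100), c("positive", "positive"))
  expect_false(res4$control_pass)

  # failing the undiluted point leaves no LOD
  res5 <- in_vitro_lod(c(0, 40), c("negative", "positive"))
  expect_false(res5$baseline_pass)
  expect_true(is.na(res5$lod))

  expect_error(in_vitro_lod(c(40, 100), c("positive", "negative")), "0%")
})

test_that("mixture series TSV export preserves the titration", {
  fit <- toy_model(c(g1 = 1, g2 = -1))
  ser <- in_silico_titration(c(g1 = 9, g2 = 1), c(g1 = 1, g2 = 9), fit,
                             grid_step = 0.1, normalize = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_mixture_series(ser, path)
  back <- utils::read.delim(path)
  expect_equal(back$p, ser$points$p)
  expect_equal(back$score, ser$points$score)
})
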