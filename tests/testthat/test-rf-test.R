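test_that("the correlation statistic matches an independent sum-formula oracle", {
  y <- c(3, 3, 3, 3, 3, 7, 13, 25, 49, 97)
  rf <- response_function(c(0, 0, 0, 0, 0, 2, 4, 8, 16, 32))
  r <- pearson_statistic(y, rf)
  expect_equal(as.numeric(r), naive_cor(y, rf$values))
  expect_false(attr(r, "degenerate"))

  v <- build_rf(effect_spec(progression = "gradual"), 4, 4)
  expect_equal(as.numeric(pearson_statistic(v$values, v)), 1)
  expect_equal(as.numeric(pearson_statistic(-v$values, v)), -1)

  set.seed(5)
  for (i in 1:20) {
    x <- rnorm(8)
    w <- response_function(rnorm(8))
    expect_equal(as.numeric(pearson_statistic(x, w)), naive_cor(x, w$values))
  }
})

test_that("constant inputs are conventioned to zero and flagged", {
  rf_const <- response_function(rep(1, 5))
  r <- pearson_statistic(rnorm(5), rf_const)
  expect_equal(as.numeric(r), 0)
  expect_true(attr(r, "degenerate"))
  r2 <- pearson_statistic(rep(2, 5), response_function(c(0, 0, 1, 1, 1)))
  expect_equal(as.numeric(r2), 0)
  expect_true(attr(r2, "degenerate"))
})

test_that("the statistic is invariant to positive affine maps of the response function", {
  set.seed(9)
  x <- rnorm(10)
  v <- c(0, 0, 0, 0, 1, 1, 2, 3, 3, 3)
  r0 <- as.numeric(pearson_statistic(x, response_function(v)))
  expect_equal(as.numeric(pearson_statistic(x, response_function(2.5 * v + 7))), r0)
  expect_equal(as.numeric(pearson_statistic(x, response_function(-v))), -r0)
})

test_that("aim orientation negates scores and hence the statistic", {
  expect_equal(orient_scores(1:3, "increase"), c(1, 2, 3))
  expect_equal(orient_scores(1:3, "decrease"), c(-1, -2, -3))
  s <- make_ab_series(c(9, 8, 9, 3, 2, 3), 3)
  d <- ab_design(6, 2, Inf, 2)
  up <- rf_test(s, d, effect_spec(aim = "increase"))
  down <- rf_test(s, d, effect_spec(aim = "decrease"))
  expect_equal(down$pseudovalues, -up$pseudovalues)
  expect_true(down$favorable)
})

test_that("a clear level shift ranks first among three admissible divisions", {
  s <- make_ab_series(c(0, 0, 0, 5, 5, 5), 3)
  tt <- rf_test(s, ab_design(6, 2, Inf, 2), effect_spec())
  # brute-force values of the three correlations
  expect_equal(tt$pseudovalues,
               c(naive_cor(s$scores, c(0, 0, 1, 1, 1, 1)),
                 1,
                 naive_cor(s$scores, c(0, 0, 0, 0, 1, 1))))
  expect_equal(tt$rank, 1L)
  expect_equal(tt$p, 1 / 3)
  expect_equal(tt$min_p, 1 / 3)
  expect_true(tt$favorable)
  expect_equal(coef(tt), c(r = 1))
})

test_that("ties and the observed value count as extreme", {
  s <- make_ab_series(c(1, 1, 2, 2, 1, 1, 2, 2), 4)
  tt <- rf_test(s, ab_design(8, 2, Inf, 2), effect_spec())
  expect_equal(tt$rank, sum(tt$pseudovalues >= tt$statistic))
  expect_equal(tt$p, tt$rank / tt$m)
  expect_gte(tt$p, tt$min_p)
})

test_that("pseudovalues match the brute-force oracle for all prototypes on small series", {
  set.seed(77)
  for (n in c(6, 8, 10)) {
    y <- round(rnorm(n, 10, 3), 2)
    s <- make_ab_series(y, n %/% 2)
    d <- ab_design(n, 2, Inf, 2)
    specs <- prototype_specs(latency = 1L, d = 2L)
    for (nm in names(specs)) {
      spec <- specs[[nm]]
      got <- rf_test(s, d, spec)
      want <- naive_ab_pseudovalues(
        y, min_a = 2, max_a = Inf, min_b = 2,
        latency = spec$latency, progression = spec$progression,
        d = if (is.null(spec$effect_duration)) NA else spec$effect_duration,
        offset = spec$offset)
      expect_equal(got$pseudovalues, want, info = paste(nm, "n =", n))
      expect_equal(got$p, sum(want >= want[s$n_A - 1]) / length(want),
                   info = paste(nm, "n =", n))
    }
    # with baseline trend added
    got_tr <- rf_test(s, d, effect_spec(trend = TRUE))
    want_tr <- naive_ab_pseudovalues(y, 2, Inf, 2, trend = TRUE)
    expect_equal(got_tr$pseudovalues, want_tr)
  }
})

test_that("divisions whose latency swallows the intervention phase are kept at zero", {
  set.seed(3)
  s <- make_ab_series(rnorm(10, 5), 4)
  tt <- rf_test(s, ab_design(10, 3, Inf, 3),
                effect_spec(onset = "delayed", latency = 5))
  # starts 4..8; at start 8 the intervention phase has 3 <= 5 occasions
  expect_equal(tt$m, 5L)
  expect_true(tt$degenerate[5])
  expect_equal(tt$pseudovalues[5], 0)
  expect_false(any(tt$degenerate[1:2]))
})

test_that("series inconsistent with the scheme are rejected", {
  s <- make_ab_series(rnorm(10), 2)   # intervention starts at occasion 3
  expect_error(rf_test(s, ab_design(10, 4, Inf, 3), effect_spec()),
               "not in the admissible set")
  expect_error(rf_test(make_ab_series(rnorm(9), 4), ab_design(10, 3, Inf, 3)),
               "length")
})

test_that("multiple-baseline statistics average the per-tier correlations", {
  set.seed(12)
  t1 <- make_ab_series(c(1, 2, 1, 9, 8, 9, 8, 9), 3)   # start 4
  t2 <- make_ab_series(c(2, 1, 2, 1, 2, 8, 9, 8), 5)   # start 6
  d <- mb_design("WW", starts = c(4, 6), n = 8)
  tt <- rf_test(list(t1, t2), d, effect_spec())
  divs <- enumerate_divisions(d)
  manual <- apply(divs, 1, function(row) {
    mean(c(naive_cor(t1$scores, c(numeric(row[1] - 1), rep(1, 8 - row[1] + 1))),
           naive_cor(t2$scores, c(numeric(row[2] - 1), rep(1, 8 - row[2] + 1)))))
  })
  expect_equal(tt$pseudovalues, manual)
  expect_equal(tt$m, 2L)
  expect_equal(tt$observed, which(divs[, 1] == 4 & divs[, 2] == 6))
})

test_that("reversal designs repeat the intervention coding in every B phase", {
  y <- c(1, 1, 1, 7, 7, 7, 1, 1, 1, 7, 7, 7)
  s <- sced_series(y, rep(c("A", "B", "A", "B"), each = 3))
  d <- abab_design(12, 4, 3)
  tt <- rf_test(s, d, effect_spec())
  expect_equal(tt$m, 1L)                       # all phases exactly minimal
  expect_equal(tt$p, 1)
  expect_equal(tt$statistic,
               naive_cor(y, c(0, 0, 0, 1, 1, 1, 0, 0, 0, 1, 1, 1)))

  d15 <- abab_design(15, 4, 3)
  s15 <- sced_series(c(rep(1, 4), rep(7, 4), rep(1, 4), rep(7, 3)),
                     rep(c("A", "B", "A", "B"), c(4, 4, 4, 3)))
  tt15 <- rf_test(s15, d15, effect_spec())
  expect_equal(tt15$m, 20L)
  expect_equal(tt15$rank, 1L)
  expect_equal(tt15$p, 1 / 20)
})

test_that("alternating treatments tests correlate with the 0/1 condition coding", {
  labs <- strsplit("ABBABAABBA", "")[[1]]
  set.seed(8)
  y <- rnorm(10, 5) + 3 * (labs == "B")
  s <- sced_series(y, labs)
  d <- atd_design(5)
  tt <- rf_test(s, d, effect_spec())
  expect_equal(tt$m, 32L)
  expect_equal(tt$statistic, naive_cor(y, as.numeric(labs == "B")))
  # p equals the proportion of admissible sequences at least as correlated
  divs <- enumerate_divisions(d)
  manual <- apply(divs, 1, function(row) naive_cor(y, as.numeric(row == "B")))
  expect_equal(tt$p, mean(manual >= tt$statistic))

  bad <- sced_series(y, rep(c("A", "B"), each = 5))  # AAAAABBBBB: block 3 is BB
  expect_error(rf_test(bad, d), "not in the admissible set")
})

test_that("two-sided tests judge extremeness on the absolute statistic", {
  s <- make_ab_series(c(9, 8, 9, 1, 2, 1), 3)   # strong unfavorable effect
  d <- ab_design(6, 2, Inf, 2)
  one <- rf_test(s, d, effect_spec())
  two <- rf_test(s, d, effect_spec(), two_sided = TRUE)
  expect_false(one$favorable)
  expect_equal(one$p, 1)                        # most negative of the set
  expect_equal(two$rank, sum(abs(two$pseudovalues) >= abs(two$statistic)))
  expect_lt(two$p, one$p)
})

test_that("masking occasions feeds through the whole test", {
  set.seed(21)
  y <- rnorm(10, 10)
  s <- make_ab_series(y, 5)
  d <- ab_design(10, 3, Inf, 3)
  tt <- rf_test(s, d, effect_spec(), exclude = c(1, 10))
  manual <- sapply(enumerate_divisions(d), function(st) {
    v <- c(numeric(st - 1), rep(1, 10 - st + 1))
    naive_cor(y[2:9], v[2:9])
  })
  expect_equal(tt$pseudovalues, manual)
})

test_that("under the null the observed rank is uniform across replicates", {
  set.seed(314)
  d <- ab_design(15, 3, Inf, 3)
  m <- n_divisions(d)
  rank1 <- 0
  reps <- 400
  for (i in seq_len(reps)) {
    start <- draw_division(d)
    s <- make_ab_series(rnorm(15), start - 1)
    rank1 <- rank1 + (rf_test(s, d, effect_spec())$rank == 1)
  }
  prop <- rank1 / reps
  expect_lt(abs(prop - 1 / m), 3 * sqrt((1 / m) * (1 - 1 / m) / reps))
})

test_that("p-value adjustments follow the standard step-down rules", {
  expect_equal(adjust_pvalues(c(0.01, 0.04), "bonferroni"), c(0.02, 0.08))
  expect_equal(adjust_pvalues(c(0.01, 0.04, 0.03), "none"), c(0.01, 0.04, 0.03))
  # Holm by hand: sorted (.01,.03,.04) * (3,2,1) -> (.03,.06,.04),
  # cumulative max -> (.03,.06,.06)
  expect_equal(adjust_pvalues(c(0.01, 0.04, 0.03), "holm"), c(0.03, 0.06, 0.06))
  p <- c(0.2, 0.04, 0.9)
  expect_true(all(adjust_pvalues(p, "holm") >= p))
  expect_true(all(adjust_pvalues(p, "bonferroni") <= 1))
})
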