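# Expected codings for the three published layouts: an immediate abrupt
# comparison with n_A = 9 / n_B = 8, an immediate gradual comparison with
# n_A = 8 / n_B = 8, and a delayed abrupt comparison with n_A = 6 / n_B = 8.

test_that("the eight prototype examples are coded as documented", {
  expect_equal(as.double(build_rf(effect_spec(), 5, 5)),
               c(0, 0, 0, 0, 0, 1, 1, 1, 1, 1))
  expect_equal(as.double(build_rf(effect_spec(duration = "temporary",
                                              effect_duration = 3), 5, 5)),
               c(0, 0, 0, 0, 0, 1, 1, 1, 0, 0))
  expect_equal(as.double(build_rf(effect_spec(progression = "gradual"), 5, 5)),
               c(0, 0, 0, 0, 0, 1, 2, 3, 4, 5))
  expect_equal(as.double(build_rf(effect_spec(progression = "gradual",
                                              duration = "temporary",
                                              effect_duration = 3), 5, 5)),
               c(0, 0, 0, 0, 0, 1, 2, 3, 2, 1))
  expect_equal(as.double(build_rf(effect_spec(onset = "delayed", latency = 2), 5, 5)),
               c(0, 0, 0, 0, 0, 0, 0, 1, 1, 1))
  expect_equal(as.double(build_rf(effect_spec(onset = "delayed", latency = 2,
                                              duration = "temporary",
                                              effect_duration = 2), 5, 5)),
               c(0, 0, 0, 0, 0, 0, 0, 1, 1, 0))
  expect_equal(as.double(build_rf(effect_spec(onset = "delayed", latency = 2,
                                              progression = "gradual"), 5, 5)),
               c(0, 0, 0, 0, 0, 0, 0, 1, 2, 3))
  expect_equal(as.double(build_rf(effect_spec(onset = "delayed", latency = 2,
                                              progression = "gradual",
                                              duration = "temporary",
                                              effect_duration = 2), 5, 5)),
               c(0, 0, 0, 0, 0, 0, 0, 1, 2, 1))
  # upper asymptote variant
  expect_equal(as.double(build_rf(effect_spec(progression = "gradual",
                                              duration = "temporary",
                                              effect_duration = 3,
                                              offset = "asymptote"), 5, 5)),
               c(0, 0, 0, 0, 0, 1, 2, 3, 3, 3))
})

test_that("immediate abrupt codings reproduce the n_A=9/n_B=8 layout column for column", {
  perm <- build_rf(effect_spec(), 9, 8)
  expect_equal(as.double(perm), c(rep(0, 9), rep(1, 8)))
  for (d in 1:5) {
    rf <- build_rf(effect_spec(duration = "temporary", effect_duration = d), 9, 8)
    expect_equal(as.double(rf), c(rep(0, 9), rep(1, d), rep(0, 8 - d)),
                 info = paste("temporary", d))
  }
})

test_that("immediate gradual codings reproduce the n_A=8/n_B=8 layout column for column", {
  expect_equal(as.double(build_rf(effect_spec(progression = "gradual"), 8, 8)),
               c(rep(0, 8), 1:8))
  expected <- list(
    `3` = c(1, 2, 3, 2, 1, 0, 0, 0),
    `4` = c(1, 2, 3, 4, 3, 2, 1, 0),
    `5` = c(1, 2, 3, 4, 5, 4, 3, 2)
  )
  for (d in names(expected)) {
    rf <- build_rf(effect_spec(progression = "gradual", duration = "temporary",
                               effect_duration = as.integer(d)), 8, 8)
    expect_equal(as.double(rf), c(rep(0, 8), expected[[d]]),
                 info = paste("gradual temporary", d))
  }
})

test_that("delayed abrupt codings reproduce the n_A=6/n_B=8 layout column for column", {
  for (L in 1:5) {
    rf <- build_rf(effect_spec(onset = "delayed", latency = L), 6, 8)
    expect_equal(as.double(rf), c(rep(0, 6), rep(0, L), rep(1, 8 - L)),
                 info = paste("delayed", L))
  }
})

test_that("baseline occasions are zero before trend addition for every spec and division", {
  for (spec in prototype_specs()) {
    for (n_A in c(1, 4, 7)) {
      for (n_B in c(4, 8)) {
        rf <- build_rf(spec, n_A, n_B)
        expect_true(all(rf$values[seq_len(n_A)] == 0))
      }
    }
  }
})

test_that("temporary at the maximal duration equals permanent", {
  for (prog in c("abrupt", "gradual")) {
    for (n_B in 3:8) {
      perm <- build_rf(effect_spec(progression = prog), 4, n_B)
      temp <- build_rf(effect_spec(progression = prog, duration = "temporary",
                                   effect_duration = n_B), 4, n_B)
      expect_equal(temp$values, perm$values, info = paste(prog, n_B))
    }
  }
})

test_that("linear trend adds 1..n and preserves the mask", {
  expect_equal(as.double(add_linear_trend(response_function(c(0, 0, 0, 1, 1, 1)))),
               c(1, 2, 3, 5, 6, 7))
  expect_equal(as.double(add_linear_trend(response_function(rep(0, 4)))),
               1:4)
  masked <- apply_mask(response_function(c(0, 0, 0, 1, 1, 1)), c(1, 6))
  tr <- add_linear_trend(masked)
  expect_equal(tr$mask, masked$mask)
  expect_equal(as.double(tr), c(NA, 2, 3, 5, 6, NA))
  # build_rf with trend = TRUE matches the documented composition
  expect_equal(as.double(build_rf(effect_spec(trend = TRUE), 3, 3)),
               c(1, 2, 3, 5, 6, 7))
})

test_that("masking excludes occasions from the statistic and validates", {
  rf <- build_rf(effect_spec(), 5, 5)
  m <- apply_mask(rf, c(1, 2, 9, 10))
  expect_equal(rf$values[m$mask], c(0, 0, 0, 1, 1, 1))
  expect_identical(apply_mask(rf, integer(0)), rf)
  # slope-focus template {NA,0,0,0,0,0,1,2,3,NA}
  slope <- apply_mask(build_rf(effect_spec(progression = "gradual"), 6, 4), c(1, 10))
  expect_equal(as.double(slope), c(NA, 0, 0, 0, 0, 0, 1, 2, 3, NA))
  expect_error(apply_mask(rf, 1:9), "fewer than two")
  expect_error(apply_mask(rf, 42), "within the series")
})

test_that("alternation coding maps two conditions to 0/1", {
  expect_equal(as.double(alternation_rf(strsplit("ABABBABAAB", "")[[1]])),
               c(0, 1, 0, 1, 1, 0, 1, 0, 0, 1))
  expect_equal(as.double(alternation_rf(c("A", "A", "A", "B", "B", "B"))),
               c(0, 0, 0, 1, 1, 1))
  expect_error(alternation_rf(c("A", "B", "C")), "two distinct")
})

test_that("a latency swallowing the intervention phase signals degeneracy", {
  expect_error(build_rf(effect_spec(onset = "delayed", latency = 4), 5, 4),
               class = "scedrf_degenerate")
  expect_error(build_rf(effect_spec(onset = "delayed", latency = 9), 5, 4),
               class = "scedrf_degenerate")
  # one effect occasion left: still buildable
  expect_equal(as.double(build_rf(effect_spec(onset = "delayed", latency = 3), 2, 4)),
               c(0, 0, 0, 0, 0, 1))
})

test_that("user-defined shapes override the built-ins and truncate to the phase", {
  spec <- effect_spec(custom = c(2, 4, 8, 16, 32))
  expect_equal(as.double(build_rf(spec, 5, 5)),
               c(0, 0, 0, 0, 0, 2, 4, 8, 16, 32))
  expect_equal(as.double(build_rf(spec, 5, 3)), c(0, 0, 0, 0, 0, 2, 4, 8))
  expect_error(build_rf(spec, 5, 6), "6 occasions")
})

test_that("built patterns agree with the loop oracle across the parameter grid", {
  for (L in 0:3) {
    for (prog in c("abrupt", "gradual")) {
      for (d in c(NA, 1, 2, 4)) {
        for (off in c("gradual", "abrupt", "asymptote")) {
          n_B <- 7
          if (L >= n_B) next
          spec <- effect_spec(
            onset = if (L == 0) "immediate" else "delayed", latency = L,
            progression = prog,
            duration = if (is.na(d)) "permanent" else "temporary",
            effect_duration = if (is.na(d)) NULL else d,
            offset = off)
          expect_equal(build_rf(spec, 3, n_B)$values,
                       c(numeric(3), naive_pattern(n_B, L, prog, d, off)),
                       info = sprintf("L=%d %s d=%s %s", L, prog, d, off))
        }
      }
    }
  }
})
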