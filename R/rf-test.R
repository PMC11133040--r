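#' Orient scores so that favorable outcomes give positive statistics
#'
#' When the aim is to decrease the target behavior, the scores are negated
#' before correlating with the response function; favorable results then
#' always correspond to positive test statistics, whatever the direction of
#' the desired change.
#'
#' @param scores numeric vector of measurements.
#' @param aim `"increase"` or `"decrease"`.
#' @return The (possibly negated) scores.
#' @export
orient_scores <- function(scores, aim = c("increase", "decrease")) {
  aim <- match.arg(aim)
  if (aim == "decrease") -as.numeric(scores) else as.numeric(scores)
}

#' Pearson correlation between a series and a response function
#'
#' The test statistic: the product-moment correlation between the observed
#' scores and the response-function constants, computed over the included
#' (unmasked) occasions.  When the response function is binary this is the
#' point-biserial correlation.  If either variable is constant on the
#' included occasions, the statistic is undefined; by convention it is set
#' to 0 and flagged via the `"degenerate"` attribute, so that degenerate
#' divisions keep their place in the randomization distribution.
#'
#' @param scores numeric vector, one score per occasion (same length as the
#'   response function).
#' @param rf a [response_function()].
#' @return A single number in `[-1, 1]` with attribute `degenerate`
#'   (`TRUE` if the statistic was conventioned to 0).
#' @examples
#' rf <- response_function(c(0, 0, 0, 0, 0, 2, 4, 8, 16, 32))
#' pearson_statistic(c(3, 3, 3, 3, 3, 7, 13, 25, 49, 97), rf)  # exactly 1
#' @export
pearson_statistic <- function(scores, rf) {
  stopifnot(inherits(rf, "response_function"))
  scores <- as.numeric(scores)
  if (length(scores) != length(rf$values)) {
    stop("'scores' and the response function must cover the same occasions",
         call. = FALSE)
  }
  x <- scores[rf$mask]
  v <- rf$values[rf$mask]
  if (any(!is.finite(x))) {
    stop("scores must be finite on the included occasions", call. = FALSE)
  }
  if (stats::var(v) == 0 || stats::var(x) == 0) {
    return(structure(0, degenerate = TRUE))
  }
  structure(as.numeric(stats::cor(x, v)), degenerate = FALSE)
}

# ---- internal division machinery -------------------------------------------

# Response-function values implied by one data division, as a list with one
# numeric vector per series (one element except for multiple-baseline
# designs).  Divisions whose pattern cannot be built (latency >= phase
# length) yield all-zero values and are flagged.
division_rfs <- function(design, spec, division) {
  build_ab <- function(n, start) {
    tryCatch(
      list(values = build_rf(spec, start - 1L, n - start + 1L)$values,
           degenerate = FALSE),
      scedrf_degenerate = function(e) list(values = rep(0, n), degenerate = TRUE)
    )
  }
  if (inherits(design, "ab_design")) {
    list(build_ab(design$n, division))
  } else if (inherits(design, "mb_design")) {
    lapply(seq_len(design$t), function(i) build_ab(design$n[i], division[i]))
  } else if (inherits(design, "abab_design")) {
    n <- design$n
    bounds <- c(1L, as.integer(division), n + 1L)
    vals <- numeric(n)
    flag <- FALSE
    for (ph in seq_len(design$phases)) {
      from <- bounds[ph]; to <- bounds[ph + 1L] - 1L
      if (ph %% 2L == 0L) {  # B phase: repeat the intervention coding
        pat <- tryCatch(intervention_pattern(spec, to - from + 1L),
                        scedrf_degenerate = function(e) NULL)
        if (is.null(pat)) flag <- TRUE else vals[from:to] <- pat
      }
    }
    if (isTRUE(spec$trend)) vals <- vals + seq_len(n)
    list(list(values = vals, degenerate = flag))
  } else if (inherits(design, "atd_design")) {
    list(list(values = as.numeric(division == "B"), degenerate = FALSE))
  } else {
    stop("unsupported design class", call. = FALSE)
  }
}

# Condition labels implied by one data division (list with one character
# vector per series).
division_labels <- function(design, division) {
  if (inherits(design, "ab_design")) {
    list(rep(c("A", "B"), c(division - 1L, design$n - division + 1L)))
  } else if (inherits(design, "mb_design")) {
    lapply(seq_len(design$t), function(i) {
      rep(c("A", "B"), c(division[i] - 1L, design$n[i] - division[i] + 1L))
    })
  } else if (inherits(design, "abab_design")) {
    lens <- diff(c(1L, as.integer(division), design$n + 1L))
    list(rep(rep_len(c("A", "B"), design$phases), lens))
  } else if (inherits(design, "atd_design")) {
    list(as.character(division))
  } else {
    stop("unsupported design class", call. = FALSE)
  }
}

# Index of the actually realized division within the enumerated set.
observed_division_index <- function(design, series, divs) {
  if (inherits(design, "ab_design")) {
    s <- series[[1L]]
    if (!s$contiguous) {
      stop("A-B designs need a contiguous A-then-B series", call. = FALSE)
    }
    idx <- which(divs == s$n_A + 1L)
  } else if (inherits(design, "mb_design")) {
    obs <- vapply(series, function(s) {
      if (!s$contiguous) {
        stop("multiple-baseline tiers need contiguous A-then-B series", call. = FALSE)
      }
      s$n_A + 1L
    }, integer(1))
    idx <- which(apply(divs, 1L, function(row) all(row == obs)))
  } else if (inherits(design, "abab_design")) {
    s <- series[[1L]]
    runs <- rle(s$labels)
    if (!identical(runs$values, rep_len(c("A", "B"), design$phases))) {
      stop(sprintf("series labels must form %d alternating phases starting with A",
                   design$phases), call. = FALSE)
    }
    obs <- cumsum(runs$lengths)[-design$phases] + 1L
    idx <- which(apply(divs, 1L, function(row) all(row == obs)))
  } else if (inherits(design, "atd_design")) {
    s <- series[[1L]]
    idx <- which(apply(divs, 1L, function(row) all(row == s$labels)))
  }
  if (length(idx) == 0L) {
    stop("the actually realized division is not in the admissible set; ",
         "series and design are inconsistent", call. = FALSE)
  }
  idx[1L]
}

#' Response-function randomization test
#'
#' Runs the randomization test: for every admissible data division of the
#' design, the response function implied by the effect specification is
#' rebuilt for that division's phase lengths and correlated (Pearson) with
#' the aim-oriented scores; the observed statistic is the one at the
#' actually realized division, and the one-sided p-value is the proportion
#' of divisions with a statistic as large as or larger than the observed
#' one (ties and the observed value itself count as extreme, so the test is
#' never anti-conservative).  For multiple-baseline designs the per-division
#' statistic is the unweighted mean of the per-tier correlations; for
#' reversal designs the intervention coding is repeated within each B
#' phase; for alternating treatments designs the response function is the
#' 0/1 condition coding of each admissible sequence.
#'
#' Divisions on which the statistic is undefined (constant response
#' function, e.g. because the latency swallows the whole intervention
#' phase) are kept in the distribution with a statistic conventioned to 0
#' and flagged; dropping them would change the size of the randomization
#' set and break the exactness of the test.
#'
#' @param series a [sced_series()], or a list of them (one per tier) for
#'   multiple-baseline designs.  Must be consistent with `design`: the
#'   realized division has to be a member of the admissible set.
#' @param design a randomization scheme from [ab_design()], [mb_design()],
#'   [abab_design()] or [atd_design()].
#' @param spec an [effect_spec()]; ignored by alternating treatments
#'   designs except for the `aim` (the coding is the 0/1 condition
#'   sequence).
#' @param exclude optional integer vector of occasion indices masked out of
#'   the statistic on every division (single-series designs only).
#' @param two_sided if `TRUE`, extremeness is judged on `abs(r)` instead of
#'   the one-sided favorable direction.
#'
#' @return An object of class `"rf_test"` with elements `statistic` (the
#'   observed Pearson r), `pseudovalues` (the statistic at every admissible
#'   division, observed included), `m`, `rank` (1 = largest), `p`
#'   (`rank/m`), `min_p` (`1/m`), `favorable` (`statistic > 0`),
#'   `degenerate` (per-division flags), `observed` (index of the realized
#'   division), `divisions`, `design`, `spec`.
#' @examples
#' s <- sced_series(c(2, 3, 2, 3, 8, 9, 8, 9, 9, 8),
#'                  rep(c("A", "B"), each = 5))
#' rf_test(s, ab_design(10, min_a = 2, min_b = 2), effect_spec())
#' @seealso [scan_durations()], [scan_latencies()], [rf_report()]
#' @export
rf_test <- function(series, design, spec = effect_spec(), exclude = NULL,
                    two_sided = FALSE) {
  stopifnot(inherits(design, "sced_design"), inherits(spec, "effect_spec"))
  if (inherits(series, "sced_series")) series <- list(series)
  if (!all(vapply(series, inherits, logical(1), "sced_series"))) {
    stop("'series' must be a sced_series or a list of them", call. = FALSE)
  }
  if (inherits(design, "mb_design")) {
    if (length(series) != design$t) {
      stop(sprintf("the design has %d tiers but %d series were supplied",
                   design$t, length(series)), call. = FALSE)
    }
    if (!is.null(exclude)) {
      stop("'exclude' is supported for single-series designs only", call. = FALSE)
    }
  } else if (length(series) != 1L) {
    stop("this design takes a single series", call. = FALSE)
  }
  expected_n <- if (inherits(design, "mb_design")) design$n else design$n
  actual_n <- vapply(series, `[[`, integer(1), "n")
  if (!all(actual_n == expected_n)) {
    stop("series length(s) do not match the design", call. = FALSE)
  }

  divs <- enumerate_divisions(design)
  m <- if (is.matrix(divs)) nrow(divs) else length(divs)
  obs_idx <- observed_division_index(design, series, divs)
  oriented <- lapply(series, function(s) orient_scores(s$scores, spec$aim))

  stat_one <- function(values, scores) {
    rf <- response_function(values)
    if (!is.null(exclude)) rf <- apply_mask(rf, exclude)
    pearson_statistic(scores, rf)
  }

  stats_vec <- numeric(m)
  degen <- logical(m)
  for (i in seq_len(m)) {
    division <- if (is.matrix(divs)) divs[i, ] else divs[i]
    rfs <- division_rfs(design, spec, division)
    per <- numeric(length(rfs))
    flg <- logical(length(rfs))
    for (j in seq_along(rfs)) {
      r <- stat_one(rfs[[j]]$values, oriented[[j]])
      per[j] <- as.numeric(r)
      flg[j] <- rfs[[j]]$degenerate || isTRUE(attr(r, "degenerate"))
    }
    stats_vec[i] <- mean(per)
    degen[i] <- any(flg)
  }
  if (all(degen)) {
    stop("the test statistic is undefined on every admissible division", call. = FALSE)
  }

  r_obs <- stats_vec[obs_idx]
  rank_obs <- if (two_sided) sum(abs(stats_vec) >= abs(r_obs)) else sum(stats_vec >= r_obs)
  structure(
    list(statistic = r_obs, pseudovalues = stats_vec, m = m,
         rank = as.integer(rank_obs), p = rank_obs / m, min_p = 1 / m,
         favorable = r_obs > 0, two_sided = isTRUE(two_sided),
         degenerate = degen, observed = obs_idx, divisions = divs,
         design = design, spec = spec, series = series),
    class = "rf_test"
  )
}

#' Adjust scan p-values for multiple testing
#'
#' Thin wrapper around [stats::p.adjust()] for the corrections offered in
#' exploratory scans.  In a purely exploratory reading the raw p-values can
#' be treated as descriptive measures; adjustment is needed when they are
#' used as probabilistic statements across several scenarios.
#'
#' @param p numeric vector of p-values.
#' @param method `"none"`, `"bonferroni"` or `"holm"`.
#' @return Adjusted p-values, capped at 1, never smaller than the input.
#' @export
adjust_pvalues <- function(p, method = c("none", "bonferroni", "holm")) {
  method <- match.arg(method)
  stats::p.adjust(p, method = method)
}

# ---- methods ---------------------------------------------------------------

#' @export
print.rf_test <- function(x, digits = 3, ...) {
  cat("Response-function randomization test\n")
  print(x$design)
  cat(sprintf("  observed Pearson r = %s (%s)\n",
              format(round(x$statistic, digits)),
              if (x$favorable) "favorable" else "unfavorable"))
  cat(sprintf("  rank %d of %d divisions; %s p = %s (minimum attainable %s)\n",
              x$rank, x$m,
              if (x$two_sided) "two-sided" else "one-sided",
              format(round(x$p, digits)), format(round(x$min_p, digits))))
  if (any(x$degenerate)) {
    cat(sprintf("  note: statistic conventioned to 0 on %d degenerate division(s)\n",
                sum(x$degenerate)))
  }
  invisible(x)
}

#' @export
summary.rf_test <- function(object, ...) {
  divs <- object$divisions
  id <- if (is.matrix(divs)) {
    apply(divs, 1L, paste, collapse = "/")
  } else {
    as.character(divs)
  }
  out <- data.frame(
    division = id,
    statistic = object$pseudovalues,
    observed = seq_along(object$pseudovalues) == object$observed,
    degenerate = object$degenerate,
    stringsAsFactors = FALSE
  )
  class(out) <- c("summary.rf_test", "data.frame")
  out
}

#' @export
coef.rf_test <- function(object, ...) c(r = object$statistic)

#' Plot the randomization distribution of an rf_test
#'
#' One point per admissible data division (statistic on the y-axis, in
#' `[-1, 1]`, with a horizontal reference line at zero); the observed
#' division is highlighted in green when the result is favorable and red
#' otherwise.
#'
#' @param x an [rf_test()] result.
#' @param main plot title.
#' @param ... further arguments passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.rf_test <- function(x, main = "Randomization distribution", ...) {
  m <- x$m
  graphics::plot(seq_len(m), x$pseudovalues, ylim = c(-1, 1), pch = 1,
                 xlab = "Admissible data division", ylab = "Pearson r",
                 main = main, ...)
  graphics::abline(h = 0, lty = 1)
  graphics::points(x$observed, x$statistic, pch = 19, cex = 1.4,
                   col = if (x$favorable) "green3" else "red")
  invisible(x)
}
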