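#' Exploratory scans over effect duration and latency
#'
#' When the exact duration of a temporary effect, or the exact latency of a
#' delayed effect, cannot be fixed a priori, the test can be repeated under
#' several operational definitions and the results compared.
#' `scan_durations()` runs the test for a permanent effect and for
#' temporary effects lasting 1, ..., `d_max` occasions;
#' `scan_latencies()` runs it for delayed effects with latencies
#' 1, ..., `l_max` (a latency of 0 reduces to the immediate specification).
#' All scenarios share the same scheme and hence the same admissible
#' divisions, so ranks and p-values are directly comparable across
#' scenarios.  Raw p-values are reported by default (as descriptive
#' measures of an exploratory analysis); Bonferroni or Holm adjustment is
#' available when the scan is used for probabilistic statements.
#'
#' @param series,design,spec,exclude,two_sided as in [rf_test()].  For
#'   `scan_durations()` the onset/progression of `spec` are kept fixed and
#'   its duration is varied; for `scan_latencies()` the progression and
#'   duration are kept and the onset latency is varied.
#' @param d_max largest temporary-effect duration to explore; truncated
#'   with a warning when it exceeds the realized intervention-phase length.
#' @param l_max largest latency to explore; truncated with a warning when
#'   it is not smaller than the realized intervention-phase length.
#' @param adjust multiplicity correction for the scenario p-values:
#'   `"none"` (default), `"bonferroni"` or `"holm"`.
#'
#' @return An object of class `"rf_scan"`: a list with a `table`
#'   data frame (one row per scenario: scenario label, scanned value,
#'   statistic, rank, `m`, raw and adjusted p, minimum attainable p,
#'   favorable and degenerate-count columns) and the full [rf_test()]
#'   `results` per scenario.
#' @examples
#' set.seed(1)
#' s <- generate_series(generation_model(delta = 4, sigma = 0.5), 9, 8)
#' scan_durations(s, ab_design(17, 4, 10, 8), effect_spec(), d_max = 5)
#' @name rf_scan
NULL

intervention_length_realized <- function(series) {
  if (inherits(series, "sced_series")) series <- list(series)
  one <- function(s) {
    if (s$contiguous) return(s$n_B)
    runs <- rle(s$labels)
    lens <- runs$lengths[runs$values == "B"]
    if (length(lens) == 0L) stop("the series has no B occasions", call. = FALSE)
    min(lens)
  }
  min(vapply(series, one, integer(1)))
}

scan_engine <- function(series, design, specs, labels, values, adjust,
                        exclude, two_sided, type) {
  results <- lapply(specs, function(sp) {
    rf_test(series, design, sp, exclude = exclude, two_sided = two_sided)
  })
  p_raw <- vapply(results, `[[`, numeric(1), "p")
  tab <- data.frame(
    scenario = labels,
    value = values,
    statistic = vapply(results, `[[`, numeric(1), "statistic"),
    rank = vapply(results, `[[`, integer(1), "rank"),
    m = vapply(results, `[[`, numeric(1), "m"),
    p = p_raw,
    p_adj = adjust_pvalues(p_raw, adjust),
    min_p = vapply(results, `[[`, numeric(1), "min_p"),
    favorable = vapply(results, `[[`, logical(1), "favorable"),
    degenerate = vapply(results, function(r) sum(r$degenerate), numeric(1)),
    stringsAsFactors = FALSE
  )
  structure(list(type = type, table = tab, results = results, adjust = adjust),
            class = "rf_scan")
}

#' @rdname rf_scan
#' @export
scan_durations <- function(series, design, spec = effect_spec(), d_max = 5L,
                           adjust = c("none", "bonferroni", "holm"),
                           exclude = NULL, two_sided = FALSE) {
  adjust <- match.arg(adjust)
  d_max <- as.integer(d_max)
  if (d_max < 1L) stop("'d_max' must be >= 1", call. = FALSE)
  n_B <- intervention_length_realized(series)
  if (d_max > n_B) {
    warning(sprintf("d_max truncated from %d to the intervention length %d",
                    d_max, n_B), call. = FALSE)
    d_max <- n_B
  }
  respec <- function(d) {
    effect_spec(aim = spec$aim, onset = spec$onset, latency = spec$latency,
                progression = spec$progression,
                duration = if (is.na(d)) "permanent" else "temporary",
                effect_duration = if (is.na(d)) NULL else d,
                offset = spec$offset, trend = spec$trend)
  }
  ds <- c(NA_integer_, seq_len(d_max))
  scan_engine(series, design, lapply(ds, respec),
              labels = c("permanent", paste0("temporary ", seq_len(d_max))),
              values = ds, adjust = adjust, exclude = exclude,
              two_sided = two_sided, type = "duration")
}

#' @rdname rf_scan
#' @export
scan_latencies <- function(series, design, spec = effect_spec(), l_max = 5L,
                           adjust = c("none", "bonferroni", "holm"),
                           exclude = NULL, two_sided = FALSE) {
  adjust <- match.arg(adjust)
  l_max <- as.integer(l_max)
  if (l_max < 1L) stop("'l_max' must be >= 1", call. = FALSE)
  n_B <- intervention_length_realized(series)
  if (l_max >= n_B) {
    warning(sprintf("l_max truncated from %d to %d (latency must leave at least one effect occasion)",
                    l_max, n_B - 1L), call. = FALSE)
    l_max <- n_B - 1L
    if (l_max < 1L) stop("the intervention phase is too short to scan latencies",
                         call. = FALSE)
  }
  respec <- function(L) {
    effect_spec(aim = spec$aim,
                onset = if (L == 0L) "immediate" else "delayed", latency = L,
                progression = spec$progression, duration = spec$duration,
                effect_duration = spec$effect_duration,
                offset = spec$offset, trend = spec$trend)
  }
  Ls <- seq_len(l_max)
  scan_engine(series, design, lapply(Ls, respec),
              labels = paste0("delayed ", Ls),
              values = Ls, adjust = adjust, exclude = exclude,
              two_sided = two_sided, type = "latency")
}

#' @export
print.rf_scan <- function(x, digits = 3, ...) {
  cat(sprintf("Exploratory %s scan (%d scenarios, %s adjustment)\n",
              x$type, nrow(x$table), x$adjust))
  tab <- x$table
  tab$statistic <- round(tab$statistic, digits)
  tab$p <- round(tab$p, digits)
  tab$p_adj <- round(tab$p_adj, digits)
  tab$min_p <- round(tab$min_p, digits)
  print(tab[, c("scenario", "statistic", "rank", "m", "p", "p_adj")],
        row.names = FALSE)
  invisible(x)
}

#' @export
summary.rf_scan <- function(object, ...) object$table

#' Plot an exploratory scan
#'
#' One panel per scenario, each showing the randomization distribution as
#' in [plot.rf_test()].
#'
#' @param x an `"rf_scan"` object.
#' @param ... passed on to [plot.rf_test()].
#' @return `x`, invisibly.
#' @export
plot.rf_scan <- function(x, ...) {
  k <- length(x$results)
  nc <- ceiling(sqrt(k))
  nr <- ceiling(k / nc)
  op <- graphics::par(mfrow = c(nr, nc), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (i in seq_len(k)) {
    plot(x$results[[i]], main = x$table$scenario[i], ...)
  }
  invisible(x)
}
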