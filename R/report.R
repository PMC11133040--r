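#' Run an analysis and write a report bundle
#'
#' One-shot driver mirroring the interactive workflow: it validates the
#' configuration, runs the randomization test (optionally as an
#' exploratory duration or latency scan), and writes to `out_dir`
#' \itemize{
#'   \item `timeseries.<ext>` -- the raw series with the phase-change line
#'     and a fixed y-axis range;
#'   \item `scenario_<k>.<ext>` -- one randomization-distribution plot per
#'     scenario (observed division green when favorable, red otherwise);
#'   \item `results.tsv` -- one row per scenario (statistic, rank, m, raw
#'     and adjusted p, minimum attainable p, flags);
#'   \item `divisions.tsv` -- one row per scenario x division (division
#'     id, statistic, observed and degenerate flags);
#'   \item `log.txt` -- a structured log of the configuration, the
#'     enumerated divisions and any degeneracy conventions.
#' }
#' All numbers in the delimited tables are exactly the [rf_test()] /
#' [rf_scan] outputs; the plots are side effects only.
#'
#' @param series a [sced_series()] (or list of tiers for multiple-baseline
#'   designs).
#' @param design a randomization scheme ([ab_design()] etc.).
#' @param spec an [effect_spec()].
#' @param out_dir output directory; created if missing.
#' @param scan `"none"` for a single test, `"duration"` or `"latency"` for
#'   an exploratory scan.
#' @param d_max,l_max scan ranges (see [scan_durations()] /
#'   [scan_latencies()]).
#' @param adjust multiplicity correction for scan p-values.
#' @param ylim optional fixed y-axis range for the time-series plot
#'   (`ylim[2]` must exceed `ylim[1]`; checked before any computation).
#' @param format `"pdf"` or `"png"` for the plot files.
#' @param exclude,two_sided passed to [rf_test()].
#' @return Invisibly, a list with the result object(s) and the paths
#'   written.
#' @export
rf_report <- function(series, design, spec = effect_spec(), out_dir,
                      scan = c("none", "duration", "latency"),
                      d_max = 5L, l_max = 5L,
                      adjust = c("none", "bonferroni", "holm"),
                      ylim = NULL, format = c("pdf", "png"),
                      exclude = NULL, two_sided = FALSE) {
  scan <- match.arg(scan)
  adjust <- match.arg(adjust)
  format <- match.arg(format)
  if (!is.null(ylim)) {
    if (length(ylim) != 2L || !all(is.finite(ylim)) || ylim[2L] <= ylim[1L]) {
      stop("'ylim' must be two finite numbers with ylim[2] > ylim[1]", call. = FALSE)
    }
  }
  if (missing(out_dir)) stop("'out_dir' is required", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  result <- switch(scan,
    none = {
      one <- rf_test(series, design, spec, exclude = exclude,
                     two_sided = two_sided)
      structure(list(type = "single",
                     table = data.frame(
                       scenario = "specified", value = NA_integer_,
                       statistic = one$statistic, rank = one$rank, m = one$m,
                       p = one$p, p_adj = one$p, min_p = one$min_p,
                       favorable = one$favorable,
                       degenerate = sum(one$degenerate),
                       stringsAsFactors = FALSE),
                     results = list(one), adjust = "none"),
                class = "rf_scan")
    },
    duration = scan_durations(series, design, spec, d_max = d_max,
                              adjust = adjust, exclude = exclude,
                              two_sided = two_sided),
    latency = scan_latencies(series, design, spec, l_max = l_max,
                             adjust = adjust, exclude = exclude,
                             two_sided = two_sided)
  )

  ext <- format
  dev_open <- function(path) {
    if (format == "pdf") grDevices::pdf(path, width = 6, height = 4)
    else grDevices::png(path, width = 720, height = 480)
  }
  paths <- character(0)

  ts_path <- file.path(out_dir, paste0("timeseries.", ext))
  dev_open(ts_path)
  first <- if (inherits(series, "sced_series")) series else series[[1L]]
  plot(first, ylim = ylim, main = "Observed series")
  grDevices::dev.off()
  paths <- c(paths, ts_path)

  for (k in seq_along(result$results)) {
    sp_path <- file.path(out_dir, sprintf("scenario_%d.%s", k, ext))
    dev_open(sp_path)
    plot(result$results[[k]], main = result$table$scenario[k])
    grDevices::dev.off()
    paths <- c(paths, sp_path)
  }

  res_path <- file.path(out_dir, "results.tsv")
  utils::write.table(result$table, res_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, res_path)

  div_rows <- do.call(rbind, lapply(seq_along(result$results), function(k) {
    s <- summary(result$results[[k]])
    data.frame(scenario = result$table$scenario[k], s,
               stringsAsFactors = FALSE)
  }))
  div_path <- file.path(out_dir, "divisions.tsv")
  utils::write.table(div_rows, div_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, div_path)

  log_path <- file.path(out_dir, "log.txt")
  con <- file(log_path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(c(
    "scedrf report log",
    paste0("design: ", class(design)[1L]),
    paste0("divisions enumerated: ", result$results[[1L]]$m),
    paste0("scan: ", scan, " | adjustment: ", adjust),
    paste0("aim: ", spec$aim, " | onset: ", spec$onset,
           " | progression: ", spec$progression,
           " | trend: ", spec$trend),
    vapply(seq_along(result$results), function(k) {
      r <- result$results[[k]]
      sprintf("scenario '%s': r = %.6f, rank %d/%d, p = %.6f, degenerate divisions: %s",
              result$table$scenario[k], r$statistic, r$rank, r$m, r$p,
              if (any(r$degenerate)) paste(which(r$degenerate), collapse = ",")
              else "none")
    }, character(1))
  ), con)
  paths <- c(paths, log_path)

  invisible(list(result = result, paths = paths))
}
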