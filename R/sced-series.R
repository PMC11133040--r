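#' Single-case experimental design series
#'
#' Container for one case's measurement series: an ordered sequence of
#' measurement occasions, each with a condition label and a numeric score.
#' Phase-design operations (A-B, multiple-baseline tiers, reversal phases)
#' require the labels to form contiguous blocks; alternation-design
#' operations accept any two-letter pattern.
#'
#' @param scores numeric vector of measurements of the target behavior, one
#'   per occasion; must be finite (missing values are not accepted -- use the
#'   response-function mask, [apply_mask()], to exclude occasions from the
#'   statistic instead).
#' @param labels character vector of single-letter condition labels, same
#'   length as `scores`.  `"A"`/`"B"` denote baseline/intervention in phase
#'   designs; alternation designs may use any two letters.
#'
#' @return An object of class `"sced_series"`: a list with elements
#'   `occasions` (1-based session indices), `labels`, `scores`, `n`, and --
#'   when the labels are a contiguous A block followed by a contiguous B
#'   block -- the phase lengths `n_A` and `n_B` (otherwise `NA`), plus the
#'   logical flag `contiguous`.
#'
#' @examples
#' s <- sced_series(c(2, 3, 2, 8, 9, 8), c("A", "A", "A", "B", "B", "B"))
#' s$n_A
#' @seealso [read_sced_file()], [rf_test()]
#' @export
sced_series <- function(scores, labels) {
  labels <- toupper(trimws(as.character(labels)))
  scores <- as.numeric(scores)
  if (length(labels) != length(scores)) {
    stop("'labels' and 'scores' must have the same length", call. = FALSE)
  }
  n <- length(scores)
  if (n < 2L) stop("a series needs at least two measurement occasions", call. = FALSE)
  if (any(!is.finite(scores))) {
    stop("all scores must be finite; missing measurements are not supported ",
         "(exclude occasions through the response-function mask instead)",
         call. = FALSE)
  }
  if (any(!grepl("^[A-Z]$", labels))) {
    stop("condition labels must be single letters (e.g. \"A\", \"B\")", call. = FALSE)
  }
  runs <- rle(labels)
  contiguous <- identical(runs$values, c("A", "B"))
  structure(
    list(
      occasions = seq_len(n),
      labels = labels,
      scores = scores,
      n = n,
      n_A = if (contiguous) as.integer(runs$lengths[1L]) else NA_integer_,
      n_B = if (contiguous) as.integer(runs$lengths[2L]) else NA_integer_,
      contiguous = contiguous
    ),
    class = "sced_series"
  )
}

#' Read a two-column SCED data file
#'
#' Reads the plain-text dialect used throughout the package: a header row
#' naming a `phase` column (condition letters) and a `score` column (numeric
#' measurements), in either order, separated by whitespace or tabs, one row
#' per measurement occasion.  Session indices are implicit in row order and
#' 1-based.
#'
#' @param path path to an existing text file.
#' @return A [sced_series()] object, rows in file order, labels upper-cased.
#' @examples
#' f <- tempfile(fileext = ".txt")
#' writeLines(c("phase score", "A 2", "A 3", "B 9", "B 8"), f)
#' read_sced_file(f)
#' @export
read_sced_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- tryCatch(
    utils::read.table(path, header = TRUE, colClasses = "character",
                      blank.lines.skip = TRUE, strip.white = TRUE,
                      stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse '", path, "': ", conditionMessage(e),
                             call. = FALSE)
  )
  names(tab) <- tolower(names(tab))
  missing_cols <- setdiff(c("phase", "score"), names(tab))
  if (length(missing_cols)) {
    stop("input file must have columns named 'phase' and 'score' (missing: ",
         paste(missing_cols, collapse = ", "), ")", call. = FALSE)
  }
  if (nrow(tab) == 0L) stop("input file contains no data rows", call. = FALSE)
  raw <- tab$score
  sc <- suppressWarnings(as.numeric(raw))
  bad <- which(is.na(sc))
  if (length(bad)) {
    stop(sprintf("non-numeric score '%s' at row %d", raw[bad[1L]], bad[1L]),
         call. = FALSE)
  }
  sced_series(sc, tab$phase)
}

#' Write a series in the two-column dialect
#'
#' @param x a [sced_series()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sced_file <- function(x, path) {
  stopifnot(inherits(x, "sced_series"))
  utils::write.table(
    data.frame(phase = x$labels, score = x$scores),
    file = path, quote = FALSE, row.names = FALSE, sep = "\t"
  )
  invisible(path)
}

#' Read a user-defined response function
#'
#' Reads a single line of comma-separated numbers defining the predicted
#' response for the intervention phase (baseline occasions are always coded
#' zero).  The file should contain as many numbers as the maximum possible
#' intervention-phase length; [build_rf()] truncates to the candidate phase
#' length.
#'
#' @param path path to a one-line text file of comma-separated numbers.
#' @return A numeric vector, order preserved.
#' @examples
#' f <- tempfile(fileext = ".txt")
#' writeLines("1, 4, 9, 16, 25", f)
#' read_user_rf(f)
#' @export
read_user_rf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("response-function file is empty", call. = FALSE)
  if (length(lines) > 1L) {
    stop("response-function file must contain a single line of ",
         "comma-separated numbers", call. = FALSE)
  }
  parts <- trimws(strsplit(lines, ",", fixed = TRUE)[[1L]])
  vals <- suppressWarnings(as.numeric(parts))
  bad <- which(is.na(vals) | !nzchar(parts))
  if (length(bad)) {
    stop(sprintf("cannot parse response-function value '%s' at position %d",
                 parts[bad[1L]], bad[1L]), call. = FALSE)
  }
  if (any(!is.finite(vals))) stop("response-function values must be finite", call. = FALSE)
  vals
}

#' @export
print.sced_series <- function(x, ...) {
  cat("Single-case series:", x$n, "measurement occasions\n")
  if (x$contiguous) {
    cat(sprintf("  A-B phase design: n_A = %d, n_B = %d (intervention starts at occasion %d)\n",
                x$n_A, x$n_B, x$n_A + 1L))
  } else {
    cat("  condition sequence:", paste(x$labels, collapse = ""), "\n")
  }
  cat("  scores:", paste(format(x$scores, trim = TRUE), collapse = ", "), "\n")
  invisible(x)
}

#' Plot a single-case series
#'
#' Time-series plot of the scores with a dashed vertical line at the phase
#' change (for contiguous A-B series).  The y-axis range can be fixed so
#' plots of different cases are comparable.
#'
#' @param x a [sced_series()] object.
#' @param ylim optional numeric length-2 vector fixing the y-axis range.
#' @param ... further arguments passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.sced_series <- function(x, ylim = NULL, ...) {
  if (!is.null(ylim)) {
    if (length(ylim) != 2L || !all(is.finite(ylim)) || ylim[2L] <= ylim[1L]) {
      stop("'ylim' must be two finite numbers with ylim[2] > ylim[1]", call. = FALSE)
    }
  }
  graphics::plot(x$occasions, x$scores, type = "b", pch = 19,
                 xlab = "Measurement occasion", ylab = "Score",
                 ylim = ylim, ...)
  if (x$contiguous) {
    graphics::abline(v = x$n_A + 0.5, lty = 2)
  } else {
    graphics::text(x$occasions, x$scores, labels = x$labels, pos = 3, cex = 0.7)
  }
  invisible(x)
}
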