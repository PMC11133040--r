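#' Response-function vectors
#'
#' A response function is a vector of constants describing the predicted
#' response at every measurement occasion; it is the template the observed
#' series is correlated with.  Occasions can be masked out of the statistic
#' (coded `NA` when printed), e.g. to focus the comparison on the last few
#' baseline and first few intervention measurements.
#'
#' @param values numeric vector, one constant per occasion.  `NA` entries
#'   are treated as masked.
#' @param mask logical vector of the same length; `FALSE` excludes the
#'   occasion from the test statistic.  Defaults to masking the `NA` entries
#'   of `values`.
#' @return An object of class `"response_function"` with elements `values`
#'   and `mask`.
#' @examples
#' response_function(c(0, 0, 0, 1, 1, 1))
#' response_function(c(NA, 0, 0, 1, 1, NA))   # focus on the middle occasions
#' @seealso [build_rf()], [apply_mask()], [alternation_rf()]
#' @export
response_function <- function(values, mask = !is.na(values)) {
  values <- as.numeric(values)
  mask <- as.logical(mask)
  if (length(mask) != length(values)) {
    stop("'mask' must have the same length as 'values'", call. = FALSE)
  }
  if (anyNA(mask)) stop("'mask' must not contain NA", call. = FALSE)
  if (sum(mask) < 2L) {
    stop("a response function needs at least two included occasions", call. = FALSE)
  }
  if (any(!is.finite(values[mask]))) {
    stop("included response-function values must be finite", call. = FALSE)
  }
  structure(list(values = values, mask = mask), class = "response_function")
}

# Classed condition signalled when a candidate data division admits no
# non-trivial predicted response (e.g. the latency swallows the whole
# intervention phase).  rf_test() catches it and conventions the statistic
# to 0 for that division so the size m of the randomization set is kept.
degenerate_rf <- function(msg) {
  stop(errorCondition(msg, class = "scedrf_degenerate"))
}

# Intervention-phase pattern implied by an effect_spec for a phase of
# n_B occasions (baseline zeros are prepended by build_rf).
intervention_pattern <- function(spec, n_B) {
  n_B <- as.integer(n_B)
  if (!is.null(spec$custom)) {
    if (length(spec$custom) < n_B) {
      stop(sprintf(paste0("user-defined response function has %d values but the ",
                          "intervention phase has %d occasions"),
                   length(spec$custom), n_B), call. = FALSE)
    }
    return(spec$custom[seq_len(n_B)])
  }
  L <- spec$latency
  if (L >= n_B) {
    degenerate_rf(sprintf(
      "latency %d leaves no effect occasions in an intervention phase of length %d",
      L, n_B))
  }
  n_eff <- n_B - L
  d <- if (spec$duration == "temporary") min(spec$effect_duration, n_eff) else n_eff
  if (spec$progression == "abrupt") {
    body <- c(rep(1, d), rep(0, n_eff - d))
  } else {
    ramp <- seq_len(d)
    rest <- n_eff - d
    tail_part <- if (rest == 0L) numeric(0)
    else switch(spec$offset,
                abrupt    = rep(0, rest),
                gradual   = pmax(d - seq_len(rest), 0),
                asymptote = rep(d, rest))
    body <- c(ramp, tail_part)
  }
  c(rep(0, L), body)
}

#' Build the response function for a candidate phase division
#'
#' Constructs the predicted-response vector implied by an [effect_spec()]
#' for an A-B comparison with `n_A` baseline and `n_B` intervention
#' occasions.  Baseline occasions are always coded zero; the
#' intervention-phase coding follows the effect pattern: abrupt effects use
#' 0/1 step coding, gradual effects ramp 1, 2, ...; delayed effects prepend
#' `latency` zeros; temporary effects wear off after `effect_duration`
#' occasions, either abruptly, by a gradual unit-per-occasion decay, or by
#' holding at an upper asymptote.  An overall linear trend 1, ..., n can be
#' added, and a user-defined shape (truncated to `n_B`) overrides the
#' built-ins.
#'
#' When the latency is at least `n_B` the division admits no effect
#' occasions at all; a classed error condition (`"scedrf_degenerate"`) is
#' signalled, which [rf_test()] catches and maps to a statistic of zero for
#' that division.
#'
#' @param spec an [effect_spec()].
#' @param n_A,n_B baseline and intervention phase lengths (each >= 1).
#' @return A [response_function()] of length `n_A + n_B`.
#' @examples
#' build_rf(effect_spec(), 5, 5)  # {0,0,0,0,0,1,1,1,1,1}
#' build_rf(effect_spec(progression = "gradual", duration = "temporary",
#'                      effect_duration = 3), 8, 8)
#' @export
build_rf <- function(spec, n_A, n_B) {
  stopifnot(inherits(spec, "effect_spec"))
  n_A <- as.integer(n_A); n_B <- as.integer(n_B)
  if (n_A < 1L || n_B < 1L) stop("phase lengths must be at least 1", call. = FALSE)
  vals <- c(rep(0, n_A), intervention_pattern(spec, n_B))
  rf <- response_function(vals)
  if (spec$trend) rf <- add_linear_trend(rf)
  rf
}

#' Add an overall linear trend to a response function
#'
#' Adds 1, 2, ..., n element-wise, representing an expected improving linear
#' trend across both phases.  The mask is preserved.
#'
#' @param rf a [response_function()].
#' @return A [response_function()] with `rf$values + seq_along(rf$values)`.
#' @examples
#' add_linear_trend(response_function(c(0, 0, 0, 1, 1, 1)))  # {1,2,3,5,6,7}
#' @export
add_linear_trend <- function(rf) {
  stopifnot(inherits(rf, "response_function"))
  response_function(rf$values + seq_along(rf$values), rf$mask)
}

#' Exclude occasions from the test statistic
#'
#' Masks the given measurement occasions out of the response function so
#' they take no part in the correlation, e.g. to compare only the last
#' three baseline and first three intervention measurements.
#'
#' @param rf a [response_function()].
#' @param excluded integer vector of 1-based occasion indices to exclude.
#' @return A [response_function()] with the updated mask; at least two
#'   occasions must remain included.
#' @examples
#' rf <- build_rf(effect_spec(), 5, 5)
#' apply_mask(rf, c(1, 2, 9, 10))
#' @export
apply_mask <- function(rf, excluded) {
  stopifnot(inherits(rf, "response_function"))
  excluded <- as.integer(excluded)
  if (length(excluded) == 0L) return(rf)
  if (any(is.na(excluded)) || any(excluded < 1L | excluded > length(rf$values))) {
    stop("'excluded' must contain occasion indices within the series", call. = FALSE)
  }
  mask <- rf$mask
  mask[excluded] <- FALSE
  if (sum(mask) < 2L) {
    stop("masking would leave fewer than two included occasions", call. = FALSE)
  }
  response_function(rf$values, mask)
}

#' Response function for an alternation design
#'
#' Codes a two-condition alternation sequence as 0 (first condition,
#' alphabetically) and 1 (second condition), occasion-aligned, for use as a
#' level-difference template in alternating treatments designs.
#'
#' @param labels character vector of condition labels with exactly two
#'   distinct letters.
#' @return A [response_function()].
#' @examples
#' alternation_rf(strsplit("ABABBABAAB", "")[[1]])
#' @export
alternation_rf <- function(labels) {
  labels <- toupper(trimws(as.character(labels)))
  u <- sort(unique(labels))
  if (length(u) != 2L) {
    stop("alternation designs support exactly two distinct conditions (got: ",
         paste(u, collapse = ", "), ")", call. = FALSE)
  }
  response_function(as.numeric(labels == u[2L]))
}

#' @export
print.response_function <- function(x, ...) {
  shown <- ifelse(x$mask, format(x$values, trim = TRUE), "NA")
  cat("Response function (", length(x$values), " occasions, ",
      sum(x$mask), " included):\n  {", paste(shown, collapse = ", "), "}\n",
      sep = "")
  invisible(x)
}

#' @export
as.double.response_function <- function(x, ...) {
  out <- x$values
  out[!x$mask] <- NA_real_
  out
}

#' @export
length.response_function <- function(x) length(x$values)
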