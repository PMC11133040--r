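#' Declarative description of an expected intervention effect
#'
#' An effect specification says what kind of change the intervention is
#' expected to produce, in terms of four dimensions that combine into the
#' eight prototypical patterns: the onset can be immediate or delayed (with a
#' latency of `latency` intervention-phase occasions showing no effect), the
#' progression abrupt (step change in level) or gradual (change in slope),
#' and the duration permanent (lasting to the end of the phase) or temporary
#' (lasting `effect_duration` occasions before wearing off).  For gradual
#' and/or temporary effects the `offset` says how the effect ends: decaying
#' gradually (one unit per occasion, mirroring how it appeared), dropping
#' abruptly to zero, or holding at an upper asymptote (no further
#' improvement, but no loss either).  An overall linear baseline trend and a
#' fully user-defined intervention-phase shape are also supported.
#'
#' @param aim `"increase"` or `"decrease"`: the desired direction of change
#'   of the target behavior.  Handled by orienting the scores (see
#'   [orient_scores()]) so that favorable results always yield positive test
#'   statistics; the response-function vectors themselves are unaffected.
#' @param onset `"immediate"` or `"delayed"`.
#' @param latency integer number of intervention-phase occasions before a
#'   delayed effect begins; `0` is equivalent to an immediate onset.
#' @param progression `"abrupt"` (0/1 step coding) or `"gradual"` (ramp
#'   coding 1, 2, ...).
#' @param duration `"permanent"` or `"temporary"`.
#' @param effect_duration integer number of occasions a temporary effect
#'   lasts before it starts to wear off (>= 1); ignored for permanent
#'   effects.
#' @param offset how a gradual/temporary effect ends: `"gradual"` (decay by
#'   one per occasion until zero; the default, mirroring the ramp),
#'   `"abrupt"` (immediate return to zero), or `"asymptote"` (hold at the
#'   peak).
#' @param trend logical; add an overall linear trend 1, 2, ..., n to the
#'   response function (improving baseline expected).
#' @param custom optional numeric vector of user-defined intervention-phase
#'   constants (e.g. from [read_user_rf()]); overrides the built-in
#'   patterns.  Must be at least as long as any candidate intervention
#'   phase; it is truncated to the phase length.
#'
#' @return An object of class `"effect_spec"`.
#' @examples
#' effect_spec()                               # immediate abrupt permanent
#' effect_spec(onset = "delayed", latency = 2) # delayed abrupt permanent
#' effect_spec(progression = "gradual", duration = "temporary",
#'             effect_duration = 3)            # ramp up then gradual decay
#' @seealso [build_rf()], [rf_test()]
#' @export
effect_spec <- function(aim = c("increase", "decrease"),
                        onset = c("immediate", "delayed"),
                        latency = if (match.arg(onset) == "delayed") 1L else 0L,
                        progression = c("abrupt", "gradual"),
                        duration = c("permanent", "temporary"),
                        effect_duration = NULL,
                        offset = c("gradual", "abrupt", "asymptote"),
                        trend = FALSE,
                        custom = NULL) {
  aim <- match.arg(aim)
  onset <- match.arg(onset)
  progression <- match.arg(progression)
  duration <- match.arg(duration)
  offset <- match.arg(offset)
  latency <- as.integer(latency)
  if (length(latency) != 1L || is.na(latency) || latency < 0L) {
    stop("'latency' must be a single integer >= 0", call. = FALSE)
  }
  if (onset == "immediate" && latency > 0L) {
    stop("an immediate onset cannot have a positive latency; use onset = \"delayed\"",
         call. = FALSE)
  }
  if (onset == "delayed" && latency == 0L) onset <- "immediate"  # 0 <=> immediate
  if (duration == "temporary") {
    if (is.null(effect_duration)) {
      stop("a temporary effect needs 'effect_duration' (number of occasions it lasts)",
           call. = FALSE)
    }
    effect_duration <- as.integer(effect_duration)
    if (length(effect_duration) != 1L || is.na(effect_duration) || effect_duration < 1L) {
      stop("'effect_duration' must be a single integer >= 1", call. = FALSE)
    }
  } else {
    effect_duration <- NULL
  }
  if (!is.null(custom)) {
    custom <- as.numeric(custom)
    if (length(custom) < 1L || any(!is.finite(custom))) {
      stop("'custom' must be a non-empty vector of finite numbers", call. = FALSE)
    }
  }
  structure(
    list(aim = aim, onset = onset, latency = latency,
         progression = progression, duration = duration,
         effect_duration = effect_duration, offset = offset,
         trend = isTRUE(trend), custom = custom),
    class = "effect_spec"
  )
}

#' @export
print.effect_spec <- function(x, ...) {
  if (!is.null(x$custom)) {
    cat("Effect specification: user-defined intervention-phase response\n")
    cat("  values:", paste(format(x$custom, trim = TRUE), collapse = ", "), "\n")
  } else {
    desc <- c(x$onset,
              if (x$onset == "delayed") sprintf("(latency %d)", x$latency),
              x$progression, x$duration,
              if (x$duration == "temporary") sprintf("(%d occasions, %s offset)",
                                                     x$effect_duration, x$offset))
    cat("Effect specification:", paste(desc, collapse = " "), "\n")
  }
  cat("  aim:", x$aim,
      if (x$trend) "| linear baseline trend added" else "", "\n")
  invisible(x)
}
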