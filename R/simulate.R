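#' Generation model for synthetic single-case series
#'
#' Describes the data-generating process used by [generate_series()] and
#' [simulate_rejection_rate()]:
#' \deqn{y_t = \mu + \beta t + \delta f_t + \epsilon_t}
#' where `f_t` is the response function of the ground-truth effect `shape`
#' at the true division, normalized to unit peak so that `delta` is the
#' effect size in score units whatever the prototype, and the errors are
#' Gaussian with standard deviation `sigma`, i.i.d. by default or
#' stationary AR(1) with lag-one autocorrelation `phi` (marginal SD kept at
#' `sigma`).  The validity of the randomization test does not rest on this
#' error model; it only shapes power curves.
#'
#' @param mu baseline level (score units).
#' @param beta per-occasion linear trend (score units per occasion).
#' @param delta effect size multiplying the unit-peak effect shape (score
#'   units).
#' @param sigma noise standard deviation (>= 0, score units).
#' @param shape an [effect_spec()] describing the true effect pattern.
#'   Its `trend` flag is ignored here: a generating trend is expressed
#'   through `beta`.
#' @param phi AR(1) autocorrelation of the errors, in (-1, 1); 0 gives
#'   i.i.d. noise.
#' @param counts if `TRUE`, scores are rounded and floored at zero to
#'   emulate behavioral counts.
#' @param seed optional integer seed applied before generating.
#' @return An object of class `"generation_model"`.
#' @export
generation_model <- function(mu = 0, beta = 0, delta = 1, sigma = 1,
                             shape = effect_spec(), phi = 0,
                             counts = FALSE, seed = NULL) {
  stopifnot(inherits(shape, "effect_spec"))
  if (sigma < 0) stop("'sigma' must be >= 0", call. = FALSE)
  if (abs(phi) >= 1) stop("'phi' must lie in (-1, 1)", call. = FALSE)
  structure(list(mu = mu, beta = beta, delta = delta, sigma = sigma,
                 shape = shape, phi = phi, counts = isTRUE(counts),
                 seed = seed),
            class = "generation_model")
}

ar1_noise <- function(n, sigma, phi) {
  if (sigma == 0) return(numeric(n))
  if (phi == 0) return(stats::rnorm(n, 0, sigma))
  innov_sd <- sigma * sqrt(1 - phi^2)
  e <- stats::rnorm(n, 0, innov_sd)
  as.numeric(stats::filter(e, phi, method = "recursive",
                           init = stats::rnorm(1, 0, sigma)))
}

generate_from_rf <- function(model, rf_values, labels) {
  peak <- max(abs(rf_values))
  f <- if (peak > 0) rf_values / peak else rf_values
  n <- length(f)
  y <- model$mu + model$beta * seq_len(n) + model$delta * f +
    ar1_noise(n, model$sigma, model$phi)
  if (model$counts) y <- pmax(round(y), 0)
  sced_series(y, labels)
}

shape_without_trend <- function(shape) {
  if (!shape$trend) return(shape)
  effect_spec(aim = shape$aim, onset = shape$onset, latency = shape$latency,
              progression = shape$progression, duration = shape$duration,
              effect_duration = shape$effect_duration, offset = shape$offset,
              trend = FALSE, custom = shape$custom)
}

#' Generate a synthetic A-B series with a known effect shape
#'
#' Draws one series of `n_A + n_B` occasions from the model: level plus
#' linear trend plus `delta` times the unit-peak-normalized response
#' function of the model's effect shape at the true division, plus noise.
#' With `sigma = 0`, `mu = 0`, `beta = 0` and `delta = 1` the generated
#' scores equal the normalized response function exactly, for every
#' prototype.
#'
#' @param model a [generation_model()].
#' @param n_A,n_B baseline and intervention phase lengths.
#' @return A [sced_series()] with contiguous A-then-B labels.
#' @examples
#' m <- generation_model(mu = 10, delta = 5, sigma = 1, seed = 42)
#' generate_series(m, 9, 8)
#' @export
generate_series <- function(model, n_A, n_B) {
  stopifnot(inherits(model, "generation_model"))
  if (!is.null(model$seed)) set.seed(model$seed)
  shape <- shape_without_trend(model$shape)
  rfv <- tryCatch(build_rf(shape, n_A, n_B)$values,
                  scedrf_degenerate = function(e) rep(0, n_A + n_B))
  generate_from_rf(model, rfv, rep(c("A", "B"), c(n_A, n_B)))
}

#' Monte-Carlo rejection rate of the randomization test
#'
#' Validity/power harness.  Each replicate (i) draws the actual division
#' uniformly from the scheme, as the design's randomization prescribes,
#' (ii) generates data whose true effect follows the model's shape at that
#' division, and (iii) runs [rf_test()] with the analysis specification
#' `spec`.  The returned value is the fraction of replicates with
#' `p <= alpha`.  Under the null (`delta = 0`) this estimates the type I
#' error rate, which for an exact test equals `floor(alpha * m) / m`; with
#' `delta != 0` it estimates power.
#'
#' @param model a [generation_model()]; `delta = 0` gives the null.
#' @param design a scheme from [ab_design()], [mb_design()],
#'   [abab_design()] or [atd_design()].
#' @param spec the analysis [effect_spec()] (what the test looks for, not
#'   necessarily the generating shape).
#' @param alpha nominal significance level in (0, 1).
#' @param reps number of Monte-Carlo replicates.
#' @param seed optional integer seed.
#' @return The rejection proportion, with attributes `se` (Monte-Carlo
#'   standard error) and `reps`.
#' @examples
#' r <- simulate_rejection_rate(generation_model(delta = 0),
#'                              ab_design(15, 3, Inf, 3), effect_spec(),
#'                              alpha = 0.1, reps = 200, seed = 7)
#' attr(r, "se")
#' @export
simulate_rejection_rate <- function(model, design, spec = effect_spec(),
                                    alpha = 0.05, reps = 1000, seed = NULL) {
  stopifnot(inherits(model, "generation_model"),
            inherits(design, "sced_design"))
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)", call. = FALSE)
  reps <- as.integer(reps)
  if (reps < 1L) stop("'reps' must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  shape <- shape_without_trend(model$shape)
  divs <- enumerate_divisions(design)
  m <- if (is.matrix(divs)) nrow(divs) else length(divs)
  hits <- logical(reps)
  for (r in seq_len(reps)) {
    i <- sample.int(m, 1L)
    division <- if (is.matrix(divs)) divs[i, ] else divs[i]
    rfs <- division_rfs(design, shape, division)
    labs <- division_labels(design, division)
    series <- mapply(function(rf, lb) generate_from_rf(model, rf$values, lb),
                     rfs, labs, SIMPLIFY = FALSE)
    if (!inherits(design, "mb_design")) series <- series[[1L]]
    res <- rf_test(series, design, spec)
    hits[r] <- res$p <= alpha
  }
  rate <- mean(hits)
  structure(rate, se = sqrt(rate * (1 - rate) / reps), reps = reps)
}
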