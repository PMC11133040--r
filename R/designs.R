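#' Randomization schemes for single-case designs
#'
#' Constructors for the four supported randomization schemes.  Each scheme
#' defines a finite set of admissible "data divisions" -- ways of splitting
#' the fixed measurement sequence into conditions -- which are all equally
#' likely under the null hypothesis and form the randomization distribution
#' of the test statistic.
#'
#' \describe{
#'   \item{`ab_design()`}{A-B phase design with a randomly chosen
#'     intervention start point.  Admissible baseline lengths `a` satisfy
#'     `min_a <= a <= min(max_a, n - min_b)`; there is one division per
#'     admissible start.}
#'   \item{`mb_design()`}{Multiple-baseline design across `t` tiers.  The
#'     Wampold-Worsham variant (`"WW"`) fixes the staggered start points and
#'     randomizes which tier receives which, giving `t!` divisions.  The
#'     Koehler-Levin variant (`"KL"`) additionally draws each position's
#'     start point from a candidate set, giving `t! * prod(set sizes)`
#'     divisions.}
#'   \item{`abab_design()`}{Reversal design with `phases` alternating
#'     phases (A1, B1, A2, B2, ...) of at least `min_length` occasions each;
#'     the divisions are all ordered tuples of phase-change points, and
#'     their number equals `choose(n - I*k + I - 1, I - 1)`.}
#'   \item{`atd_design()`}{Alternating treatments design with block
#'     randomization: `blocks` consecutive blocks of two occasions, each
#'     containing conditions A and B in random order, giving `2^blocks`
#'     divisions.}
#' }
#'
#' @param n series length (per tier for `mb_design`; scalars are recycled
#'   across tiers).
#' @param min_a,max_a,min_b minimum/maximum baseline length and minimum
#'   intervention length for `ab_design`.
#' @param variant `"WW"` (Wampold-Worsham) or `"KL"` (Koehler-Levin).
#' @param starts for `"WW"`, an integer vector of fixed staggered
#'   intervention start occasions, one per tier; for `"KL"`, a list of
#'   integer candidate-start sets, one per stagger position.
#' @param phases number of phases `I` for the reversal design.
#' @param min_length minimal phase length `k`.
#' @param blocks number of two-occasion blocks `b` for the alternating
#'   treatments design.
#'
#' @return An object of class `c("<type>_design", "sced_design")` holding
#'   the scheme parameters.
#' @examples
#' ab_design(15, min_a = 3, min_b = 3)        # 10 admissible start points
#' mb_design("WW", starts = 4:7, n = 15)      # 4! = 24 tier orders
#' abab_design(15, phases = 4, min_length = 3)
#' atd_design(blocks = 5)
#' @seealso [enumerate_divisions()], [n_divisions()], [draw_division()],
#'   [rf_test()]
#' @name sced_designs
NULL

#' @rdname sced_designs
#' @export
ab_design <- function(n, min_a = 3L, max_a = Inf, min_b = 3L) {
  n <- as.integer(n)
  min_a <- as.integer(min_a)
  min_b <- as.integer(min_b)
  if (n < 2L) stop("'n' must be at least 2", call. = FALSE)
  if (min_a < 1L || min_b < 1L) stop("minimum phase lengths must be >= 1", call. = FALSE)
  hi <- min(max_a, n - min_b)
  if (hi < min_a) {
    stop("no admissible divisions: the constraints leave no valid baseline length",
         call. = FALSE)
  }
  structure(list(n = n, min_a = min_a, max_a = max_a, min_b = min_b),
            class = c("ab_design", "sced_design"))
}

#' @rdname sced_designs
#' @export
mb_design <- function(variant = c("WW", "KL"), starts, n) {
  variant <- match.arg(variant)
  if (variant == "WW") {
    starts <- as.integer(starts)
    t <- length(starts)
    if (t < 1L) stop("'starts' must name at least one tier", call. = FALSE)
    if (anyDuplicated(starts)) {
      stop("Wampold-Worsham start points must be distinct (staggered)", call. = FALSE)
    }
    start_sets <- as.list(starts)
  } else {
    if (!is.list(starts)) stop("for the KL variant, 'starts' must be a list of candidate sets",
                               call. = FALSE)
    start_sets <- lapply(starts, as.integer)
    t <- length(start_sets)
    if (t < 1L || any(lengths(start_sets) == 0L)) {
      stop("each Koehler-Levin candidate set must be non-empty", call. = FALSE)
    }
    all_starts <- unlist(start_sets)
    if (anyDuplicated(all_starts)) {
      warning("Koehler-Levin candidate start sets overlap across positions; ",
              "the enumeration keeps one division per (order, choice) combination",
              call. = FALSE)
    }
  }
  n <- as.integer(rep_len(n, t))
  lo <- vapply(start_sets, min, integer(1))
  hi <- vapply(start_sets, max, integer(1))
  if (any(lo < 2L) || any(hi > n)) {
    stop("start points must lie in 2..n so both phases are non-empty", call. = FALSE)
  }
  structure(list(variant = variant, start_sets = start_sets, t = t, n = n),
            class = c("mb_design", "sced_design"))
}

#' @rdname sced_designs
#' @export
abab_design <- function(n, phases = 4L, min_length = 3L) {
  n <- as.integer(n); I <- as.integer(phases); k <- as.integer(min_length)
  if (I < 2L) stop("a reversal design needs at least 2 phases", call. = FALSE)
  if (I %% 2L != 0L) stop("'phases' must be even (A and B phases alternate)", call. = FALSE)
  if (k < 1L) stop("'min_length' must be >= 1", call. = FALSE)
  if (n < I * k) {
    stop(sprintf("infeasible design: n = %d < phases * min_length = %d", n, I * k),
         call. = FALSE)
  }
  structure(list(n = n, phases = I, min_length = k),
            class = c("abab_design", "sced_design"))
}

#' @rdname sced_designs
#' @export
atd_design <- function(blocks) {
  b <- as.integer(blocks)
  if (b < 1L) stop("'blocks' must be >= 1", call. = FALSE)
  structure(list(blocks = b, n = 2L * b),
            class = c("atd_design", "sced_design"))
}

#' Enumerate the admissible data divisions of a scheme
#'
#' Returns every admissible division of the measurement sequence under the
#' design's randomization procedure, in a deterministic, duplicate-free
#' order.  The representation depends on the design:
#' \itemize{
#'   \item A-B: integer vector of intervention start occasions (ascending);
#'   \item multiple-baseline: integer matrix, one row per division, column
#'     `i` the intervention start occasion of tier `i`;
#'   \item reversal: integer matrix, one row per division, the `I - 1`
#'     phase-change occasions (first occasion of each new phase, 1-based);
#'   \item alternating treatments: character matrix, one row per division,
#'     the per-occasion condition labels.
#' }
#'
#' @param design a scheme from [ab_design()], [mb_design()],
#'   [abab_design()] or [atd_design()].
#' @param ... unused.
#' @return See Details; the number of rows/elements always equals
#'   [n_divisions()].
#' @examples
#' enumerate_divisions(ab_design(15, 3, Inf, 3))
#' nrow(enumerate_divisions(abab_design(15, 4, 3)))  # 20
#' @export
enumerate_divisions <- function(design, ...) UseMethod("enumerate_divisions")

#' @export
enumerate_divisions.ab_design <- function(design, ...) {
  a <- seq.int(design$min_a, min(design$max_a, design$n - design$min_b))
  as.integer(a + 1L)  # intervention start occasions
}

# all permutations of a vector, rows in lexicographic index order
permutations_of <- function(v) {
  t <- length(v)
  if (t == 1L) return(matrix(v, 1L, 1L))
  out <- vector("list", t)
  for (i in seq_len(t)) {
    rest <- permutations_of(v[-i])
    out[[i]] <- cbind(v[i], rest, deparse.level = 0)
  }
  do.call(rbind, out)
}

#' @export
enumerate_divisions.mb_design <- function(design, ...) {
  t <- design$t
  # rows assign stagger positions to tiers: column i = position given to tier i
  pos_perms <- permutations_of(seq_len(t))
  if (design$variant == "WW") {
    starts <- vapply(design$start_sets, identity, integer(1))
    out <- matrix(starts[pos_perms], nrow = nrow(pos_perms))
  } else {
    rows <- vector("list", nrow(pos_perms))
    for (r in seq_len(nrow(pos_perms))) {
      sets <- design$start_sets[pos_perms[r, ]]
      grid <- as.matrix(expand.grid(sets, KEEP.OUT.ATTRS = FALSE))
      dimnames(grid) <- NULL
      rows[[r]] <- grid
    }
    out <- do.call(rbind, rows)
  }
  storage.mode(out) <- "integer"
  colnames(out) <- paste0("tier", seq_len(t))
  out
}

# ordered compositions of n into 'parts' parts each >= k
phase_compositions <- function(n, parts, k) {
  if (parts == 1L) {
    return(if (n >= k) matrix(n, 1L, 1L) else matrix(integer(0), 0L, 1L))
  }
  out <- list()
  for (l in seq.int(k, n - (parts - 1L) * k)) {
    rest <- phase_compositions(n - l, parts - 1L, k)
    if (nrow(rest)) out[[length(out) + 1L]] <- cbind(l, rest, deparse.level = 0)
  }
  do.call(rbind, out)
}

#' @export
enumerate_divisions.abab_design <- function(design, ...) {
  comp <- phase_compositions(design$n, design$phases, design$min_length)
  # change points: first occasion of phases 2..I
  cs <- t(apply(comp, 1L, cumsum))                     # one row per division
  cp <- cs[, -design$phases, drop = FALSE] + 1L
  storage.mode(cp) <- "integer"
  colnames(cp) <- paste0("change", seq_len(design$phases - 1L))
  cp
}

#' @export
enumerate_divisions.atd_design <- function(design, ...) {
  b <- design$blocks
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), b), KEEP.OUT.ATTRS = FALSE)
  out <- matrix("", nrow(grid), 2L * b)
  for (j in seq_len(b)) {
    flipped <- grid[[j]]
    out[, 2L * j - 1L] <- ifelse(flipped, "B", "A")
    out[, 2L * j]      <- ifelse(flipped, "A", "B")
  }
  colnames(out) <- paste0("occ", seq_len(2L * b))
  out
}

#' Closed-form number of admissible randomizations
#'
#' Counts the admissible data divisions of a scheme in closed form; always
#' equals the enumeration length.  A design should allow at least 20
#' randomizations for a p-value as small as 0.05 to be attainable.
#'
#' @inheritParams enumerate_divisions
#' @return A single number.
#' @examples
#' n_divisions(mb_design("WW", starts = 4:10, n = 18))  # 7! = 5040
#' n_divisions(atd_design(5))                           # 2^5 = 32
#' @export
n_divisions <- function(design, ...) UseMethod("n_divisions")

#' @export
n_divisions.ab_design <- function(design, ...) {
  as.numeric(min(design$max_a, design$n - design$min_b) - design$min_a + 1L)
}

#' @export
n_divisions.mb_design <- function(design, ...) {
  factorial(design$t) * prod(lengths(design$start_sets))
}

#' @export
n_divisions.abab_design <- function(design, ...) {
  I <- design$phases
  choose(design$n - I * design$min_length + I - 1L, I - 1L)
}

#' @export
n_divisions.atd_design <- function(design, ...) 2^design$blocks

#' Draw one data division uniformly at random
#'
#' Samples a single admissible division with equal probability, as the
#' randomization step performed before data collection.  Uses R's RNG; set
#' the seed (or pass `seed`) for reproducibility.
#'
#' @inheritParams enumerate_divisions
#' @param seed optional integer seed applied via [set.seed()] before
#'   drawing.
#' @return One division in the same representation as one element/row of
#'   [enumerate_divisions()].
#' @export
draw_division <- function(design, seed = NULL) {
  stopifnot(inherits(design, "sced_design"))
  if (!is.null(seed)) set.seed(seed)
  divs <- enumerate_divisions(design)
  if (is.matrix(divs)) {
    divs[sample.int(nrow(divs), 1L), ]
  } else {
    divs[sample.int(length(divs), 1L)]
  }
}

#' @export
print.sced_design <- function(x, ...) {
  lab <- switch(class(x)[1L],
    ab_design = sprintf("A-B design, n = %d, baseline %d..%s, intervention >= %d",
                        x$n, x$min_a,
                        if (is.finite(x$max_a)) format(x$max_a) else "n-min_b",
                        x$min_b),
    mb_design = sprintf("multiple-baseline design (%s), %d tiers",
                        if (x$variant == "WW") "Wampold-Worsham" else "Koehler-Levin",
                        x$t),
    abab_design = sprintf("reversal design, n = %d, %d phases of >= %d occasions",
                          x$n, x$phases, x$min_length),
    atd_design = sprintf("alternating treatments design, %d blocks (n = %d)",
                         x$blocks, x$n))
  cat(lab, "\n")
  cat("  admissible randomizations:", format(n_divisions(x)), "\n")
  invisible(x)
}
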