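# Independent brute-force oracles, written loop-style on purpose: they share
# no code with the package internals and serve as the reference the vectorized
# implementation is checked against.

# plain sum-formula Pearson correlation
naive_cor <- function(x, v) {
  n <- length(x)
  mx <- sum(x) / n
  mv <- sum(v) / n
  num <- 0; dx <- 0; dv <- 0
  for (i in seq_len(n)) {
    num <- num + (x[i] - mx) * (v[i] - mv)
    dx <- dx + (x[i] - mx)^2
    dv <- dv + (v[i] - mv)^2
  }
  if (dx == 0 || dv == 0) return(NA_real_)
  num / sqrt(dx * dv)
}

# intervention-phase coding built with explicit loops
naive_pattern <- function(n_B, latency, progression, d = NA, offset = "gradual") {
  out <- numeric(n_B)
  if (latency >= n_B) return(out)  # degenerate: no effect occasions
  n_eff <- n_B - latency
  dd <- if (is.na(d)) n_eff else min(d, n_eff)
  level <- 0
  for (j in seq_len(n_B)) {
    if (j <= latency) { out[j] <- 0; next }
    k <- j - latency   # position within the effect window
    if (progression == "abrupt") {
      out[j] <- if (k <= dd) 1 else 0
    } else {
      if (k <= dd) {
        out[j] <- k
      } else if (offset == "abrupt") {
        out[j] <- 0
      } else if (offset == "asymptote") {
        out[j] <- dd
      } else {
        val <- dd - (k - dd)
        out[j] <- if (val > 0) val else 0
      }
    }
  }
  out
}

# every pseudovalue of an A-B start-point randomization test, by loops
naive_ab_pseudovalues <- function(y, min_a, max_a, min_b, latency = 0,
                                  progression = "abrupt", d = NA,
                                  offset = "gradual", trend = FALSE,
                                  aim = "increase") {
  n <- length(y)
  if (aim == "decrease") y <- -y
  hi <- min(max_a, n - min_b)
  out <- numeric(0)
  for (a in min_a:hi) {
    v <- c(numeric(a), naive_pattern(n - a, latency, progression, d, offset))
    if (trend) for (i in seq_len(n)) v[i] <- v[i] + i
    r <- naive_cor(y, v)
    if (is.na(r)) r <- 0   # degenerate convention
    out <- c(out, r)
  }
  out
}

make_ab_series <- function(scores, n_A) {
  sced_series(scores, rep(c("A", "B"), c(n_A, length(scores) - n_A)))
}

# the eight prototypical effect specifications (latency 2, duration 3 where
# the dimension applies)
prototype_specs <- function(latency = 2L, d = 3L) {
  list(
    iap = effect_spec(),
    iat = effect_spec(duration = "temporary", effect_duration = d),
    igp = effect_spec(progression = "gradual"),
    igt = effect_spec(progression = "gradual", duration = "temporary",
                      effect_duration = d),
    dap = effect_spec(onset = "delayed", latency = latency),
    dat = effect_spec(onset = "delayed", latency = latency,
                      duration = "temporary", effect_duration = d),
    dgp = effect_spec(onset = "delayed", latency = latency,
                      progression = "gradual"),
    dgt = effect_spec(onset = "delayed", latency = latency,
                      progression = "gradual", duration = "temporary",
                      effect_duration = d)
  )
}
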