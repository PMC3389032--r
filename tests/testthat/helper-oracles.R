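# Independent oracles used across the suite.  They deliberately share no
# code with the package internals they check.

# Classical RK4 integration of dLHp/dt = LH(t) - a * LHp, with the release
# rate LH(t) = sum_k A_k exp(-gamma (t - s_k)) for s_k <= t.  Integrates
# piecewise between spike arrivals (where the release rate jumps) so every
# integrated segment is smooth.
rk4_plasma <- function(spike_times, spike_amps, gamma, a, eval_times,
                       lhp0 = 0, step = 0.01) {
  eval_times <- sort(eval_times)
  stopifnot(eval_times[1] == 0)
  # integrate segment-wise so that every evaluation time is hit exactly and
  # every segment is smooth (split at the release-rate jumps)
  breaks <- sort(unique(c(eval_times,
                          spike_times[spike_times > 0 &
                                        spike_times < max(eval_times)])))
  x <- lhp0
  out <- numeric(length(eval_times))
  out[1] <- lhp0
  j <- 2L
  for (s in seq_len(length(breaks) - 1L)) {
    t0 <- breaks[s]; t1 <- breaks[s + 1L]
    # spikes active on this smooth segment: arrived at or before its start
    # (a spike landing exactly at t1 only acts from the next segment on)
    act <- spike_times <= t0 + 1e-9
    f <- function(t, x) {
      rel <- if (any(act))
        sum(spike_amps[act] * exp(-gamma * (t - spike_times[act])))
      else 0
      rel - a * x
    }
    n <- max(1L, ceiling((t1 - t0) / step))
    h <- (t1 - t0) / n
    t <- t0
    for (i in seq_len(n)) {
      k1 <- f(t, x)
      k2 <- f(t + h / 2, x + h / 2 * k1)
      k3 <- f(t + h / 2, x + h / 2 * k2)
      k4 <- f(t + h, x + h * k3)
      x <- x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t0 + i * h
    }
    if (j <= length(eval_times) && isTRUE(all.equal(t1, eval_times[j]))) {
      out[j] <- x
      j <- j + 1L
    }
  }
  list(times = eval_times, levels = out)
}

# Brute-force height/magnitude/relative-magnitude recomputation straight
# from the definitions, via explicit loops.
brute_height <- function(y, i) {
  m <- y[1]
  for (v in y) if (v < m) m <- v
  y[i] - m
}

brute_magnitude <- function(y, P, i) {
  N <- length(y)
  prev <- 1L
  for (p in P) if (p < i && p > prev) prev <- p
  if (!any(P < i)) prev <- 1L
  nxt <- N
  for (p in rev(P)) if (p > i && p < nxt) nxt <- p
  if (!any(P > i)) nxt <- N
  U <- y[i] - min(y[prev:i])
  V <- y[i] - min(y[i:nxt])
  if (U <= 0 || V <= 0) return(0)
  sqrt(U * V)
}

brute_relative_magnitude <- function(y, i, j) {
  lo <- min(i, j); hi <- max(i, j)
  m <- min(y[lo:hi])
  u <- y[lo] - m; v <- y[hi] - m
  if (u <= 0 || v <= 0) return(0)
  sqrt(u * v)
}

# Normal-equations least squares for a polynomial fit; columns are scaled
# to unit norm so the raw-power basis stays solvable for times in minutes.
brute_polyfit <- function(t, v, degree) {
  X <- outer(t, 0:degree, `^`)
  d <- sqrt(colSums(X^2))
  Xs <- sweep(X, 2, d, `/`)
  z <- solve(crossprod(Xs), crossprod(Xs, v))
  as.numeric(z / d)
}

# A jagged random series with guaranteed alternation, for small-sample
# oracle comparisons.
random_small_series <- function(n, seed) {
  set.seed(seed)
  abs(cumsum(rnorm(n))) + runif(n, 0, 2) + 0.5
}

# Hand-built sampled series: a six-sample asymmetric pulse template
# repeated on a flat baseline; `heights` gives one peak height per pulse.
# The summit of pulse p sits at index 6 p - 2.
toy_pulse_series <- function(heights, baseline = 0.1, Ts = 10) {
  template <- c(0, 1, 0.55, 0.3, 0.15, 0.05)
  y <- rep(baseline, 2L)
  for (h in heights)
    y <- c(y, baseline + h * template)
  dynpeak:::as_sampled_series(
    data.frame(time = Ts * (seq_along(y) - 1) + 1, value = y), Ts = Ts)
}
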