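#' Piecewise-linear release profile of pulsatile pituitary secretion
#'
#' Describes the time-varying control of LH release by the pituitary gland:
#' a spike amplitude function \eqn{A(t)} (ng/ml/min), an interspike-interval
#' function \eqn{I(t)} (min), and the within-spike half-life \eqn{h} (min) of
#' the exponentially decaying release rate.  The secretion term is a train of
#' jumps of size \eqn{A(s_k)} at spike times \eqn{s_k}, each followed by an
#' exponential decay at rate \eqn{\gamma = \ln 2 / h}.
#'
#' `amplitude` and `ipi` accept three forms:
#' a single number (constant over the record), a length-2 vector
#' `c(start, end)` (linear ramp over `[0, duration]`), or a two-column
#' matrix / data frame of `(time, value)` breakpoints interpolated linearly
#' and extended as constants beyond the terminal breakpoints.
#'
#' @param amplitude spike amplitude specification, ng/ml/min (see Details).
#' @param ipi interspike-interval specification, min (see Details).
#' @param half_life within-spike half-life \eqn{h} of the release rate, min.
#'   Must be much shorter than the plasma clearance half-life; a warning is
#'   issued above 10 min.
#' @param duration length of the simulated record, min.
#' @return An object of class `release_profile` with elements
#'   `amplitude_fn`, `ipi_fn` (vectorised functions of time), `half_life`,
#'   `gamma` and `duration`.
#' @examples
#' prof <- release_profile(amplitude = 1, ipi = 60, duration = 600)
#' prof$ipi_fn(c(0, 300))
#' ramp <- release_profile(amplitude = c(15, 6.5), ipi = c(80, 50),
#'                         duration = 1000)
#' @export
release_profile <- function(amplitude, ipi, half_life = 2, duration = 1000) {
  if (!is.numeric(duration) || length(duration) != 1L || duration <= 0)
    stop("'duration' must be a positive number of minutes")
  if (!is.numeric(half_life) || length(half_life) != 1L || half_life <= 0)
    stop("'half_life' must be a positive number of minutes")
  if (half_life > 10)
    warning("'half_life' above 10 min is long compared with plasma ",
            "clearance; spikes and pulses will blur into each other")
  amplitude_fn <- pw_linear_fn(amplitude, duration, "amplitude")
  ipi_fn <- pw_linear_fn(ipi, duration, "ipi")
  probe <- seq(0, duration, length.out = 257L)
  if (any(amplitude_fn(probe) <= 0))
    stop("'amplitude' must be positive over the whole record")
  if (any(ipi_fn(probe) <= 0))
    stop("'ipi' must be positive over the whole record")
  structure(
    list(amplitude_fn = amplitude_fn, ipi_fn = ipi_fn,
         half_life = half_life, gamma = decay_rate_from_half_life(half_life),
         duration = duration),
    class = "release_profile")
}

## Turn a constant / ramp / breakpoint spec into a vectorised function of
## time, linear between knots, constant beyond them.
pw_linear_fn <- function(spec, duration, what) {
  if (is.data.frame(spec)) spec <- as.matrix(spec)
  if (is.matrix(spec)) {
    if (ncol(spec) != 2L || nrow(spec) < 1L)
      stop("'", what, "' breakpoints must be a two-column (time, value) table")
    tt <- spec[, 1L]; vv <- spec[, 2L]
    if (is.unsorted(tt, strictly = TRUE))
      stop("'", what, "' breakpoint times must be strictly increasing")
  } else if (is.numeric(spec) && length(spec) == 1L) {
    v <- spec
    return(function(t) rep_len(v, length(t)))
  } else if (is.numeric(spec) && length(spec) == 2L) {
    tt <- c(0, duration); vv <- spec
  } else {
    stop("'", what, "' must be a number, a c(start, end) ramp or a ",
         "(time, value) table")
  }
  if (length(tt) == 1L) {
    v <- vv[1L]
    return(function(t) rep_len(v, length(t)))
  }
  function(t) stats::approx(tt, vv, xout = t, rule = 2)$y
}

#' Exponential decay rate from a half-life
#'
#' @param h half-life, min.
#' @return The first-order rate constant \eqn{\ln 2 / h}, per min.
#' @examples
#' decay_rate_from_half_life(60)   # plasma clearance for a 1 h pulse half-life
#' @export
decay_rate_from_half_life <- function(h) {
  if (!is.numeric(h) || length(h) != 1L || !is.finite(h) || h <= 0)
    stop("half-life 'h' must be a positive finite number")
  log(2) / h
}

#' Generate the spike train of a release profile
#'
#' Spike times are generated iteratively from the interspike-interval
#' function: the first spike occurs at \eqn{t = 0} and each next spike at
#' \eqn{s_{k+1} = s_k + I(s_k)}; generation stops once a candidate time
#' exceeds the record duration.  Each spike carries amplitude \eqn{A(s_k)}.
#'
#' @param profile a [release_profile()].
#' @return An object of class `spike_train`: a list with `times` (min,
#'   strictly increasing, starting at 0) and `amplitudes` (ng/ml/min).
#' @examples
#' train <- build_spike_train(release_profile(1, 100, duration = 1000))
#' train$times   # 0, 100, ..., 1000
#' @export
build_spike_train <- function(profile) {
  stopifnot(inherits(profile, "release_profile"))
  times <- numeric(0)
  s <- 0
  while (s <= profile$duration) {
    times <- c(times, s)
    step <- profile$ipi_fn(s)
    if (!is.finite(step) || step <= 0)
      stop("interspike-interval function returned a non-positive value at t = ", s)
    s <- s + step
  }
  structure(list(times = times, amplitudes = profile$amplitude_fn(times)),
            class = "spike_train")
}

#' Plasma hormone level driven by a spike train
#'
#' Integrates the clearance equation
#' \eqn{dLH_p/dt = LH(t) - a\,LH_p(t)} on a fine regular grid, where the
#' release rate \eqn{LH(t)} is the sum of exponentially decaying spikes of
#' the train.  The linear structure gives the closed-form superposition
#' \deqn{LH_p(t) = LH_p(0)e^{-at} + \sum_{s_k \le t}
#'   \frac{A_k}{\gamma - a}\left(e^{-a(t-s_k)} - e^{-\gamma(t-s_k)}\right),}
#' with the degenerate limit \eqn{A_k (t-s_k) e^{-a(t-s_k)}} when
#' \eqn{\gamma = a}.
#'
#' @param train a [spike_train()].
#' @param gamma within-spike decay rate of the release rate, per min.
#' @param a plasma clearance rate, per min; the default encodes the one-hour
#'   half-life of LH pulses in jugular blood.
#' @param grid_step grid resolution, min (at most 0.1).
#' @param duration record length, min.
#' @param lhp0 initial plasma level, ng/ml.
#' @return An object of class `plasma_signal`: list with `grid_times`,
#'   `levels` (ng/ml), `a`, `gamma` and the `spike_train`.
#' @seealso [simulate_plasma()] for the one-call wrapper from a profile.
#' @export
integrate_plasma <- function(train, gamma, a = log(2) / 60, grid_step = 0.05,
                             duration, lhp0 = 0) {
  stopifnot(inherits(train, "spike_train"))
  if (grid_step <= 0 || grid_step > 0.1)
    stop("'grid_step' must be in (0, 0.1] min")
  if (gamma <= 0 || a <= 0) stop("rates 'gamma' and 'a' must be positive")
  if (lhp0 < 0) stop("'lhp0' must be non-negative")
  tt <- seq(0, duration, by = grid_step)
  levels <- lhp0 * exp(-a * tt)
  for (k in seq_along(train$times)) {
    sk <- train$times[k]
    if (sk > duration) break
    on <- tt >= sk
    dt <- tt[on] - sk
    contrib <- if (abs(gamma - a) < 1e-12) {
      train$amplitudes[k] * dt * exp(-a * dt)
    } else {
      train$amplitudes[k] / (gamma - a) * (exp(-a * dt) - exp(-gamma * dt))
    }
    levels[on] <- levels[on] + contrib
  }
  structure(list(grid_times = tt, levels = levels, a = a, gamma = gamma,
                 spike_train = train),
            class = "plasma_signal")
}

#' Simulate the plasma signal of a release profile
#'
#' Convenience wrapper: builds the spike train of `profile` and integrates
#' the clearance equation over the profile duration.  By default the train
#' is extended `burn_in` minutes before the record start (with the
#' amplitude and interval the profile takes at time 0), so that the signal
#' is in its periodic steady state when the record begins instead of
#' rising from an empty compartment; pulses of the burn-in period are not
#' reported by [theoretical_pulses()].
#'
#' @inheritParams integrate_plasma
#' @param profile a [release_profile()].
#' @param burn_in length of the pre-record secretion history, min.  The
#'   default of 600 min (ten clearance half-lives) leaves a residual
#'   transient of about one percent; use 0 for a signal starting from
#'   `lhp0`.
#' @return A `plasma_signal` (see [integrate_plasma()]).
#' @examples
#' sig <- simulate_plasma(release_profile(1, 60, duration = 400))
#' max(sig$levels)
#' @export
simulate_plasma <- function(profile, a = log(2) / 60, grid_step = 0.05,
                            lhp0 = 0, burn_in = 600) {
  train <- build_spike_train(profile)
  if (burn_in > 0) {
    step <- profile$ipi_fn(0)
    pre <- rev(seq(-step, -burn_in, by = -step))
    train$times <- c(pre, train$times)
    train$amplitudes <- c(profile$amplitude_fn(pre), train$amplitudes)
  }
  integrate_plasma(train, gamma = profile$gamma, a = a,
                   grid_step = grid_step, duration = profile$duration,
                   lhp0 = lhp0)
}

#' Theoretical pulses of a plasma signal
#'
#' For each secretory spike, the theoretical pulse amplitude is the maximal
#' plasma level reached during the event, i.e. the local maximum of
#' \eqn{LH_p} between that spike and the next, and the theoretical pulse
#' time is its location on the grid.  When the interspike interval is
#' shorter than the rise time the maxima are unresolved; such entries are
#' flagged rather than dropped.
#'
#' @param signal a `plasma_signal`.
#' @return A data frame with one row per spike: `spike_time`, `pulse_time`,
#'   `amplitude` (ng/ml) and logical `flagged` for unresolved events.
#' @export
theoretical_pulses <- function(signal) {
  stopifnot(inherits(signal, "plasma_signal"))
  st_all <- signal$spike_train$times
  tt <- signal$grid_times
  if (length(st_all) == 0L || length(tt) == 0L) stop("empty plasma signal")
  keep <- which(st_all >= 0)        # burn-in spikes only shape the baseline
  st <- st_all[keep]
  if (length(st) == 0L) stop("no spikes inside the record")
  bounds <- c(st, tt[length(tt)] + diff(tt[1:2]))
  out <- data.frame(spike_time = st, pulse_time = NA_real_,
                    amplitude = NA_real_, flagged = FALSE)
  for (k in seq_along(st)) {
    in_win <- which(tt > bounds[k] & tt <= bounds[k + 1L])
    if (length(in_win) == 0L) { out$flagged[k] <- TRUE; next }
    rel <- which.max(signal$levels[in_win])
    out$pulse_time[k] <- tt[in_win[rel]]
    out$amplitude[k] <- signal$levels[in_win[rel]]
    # a maximum pinned at the window end never descended: unresolved event
    out$flagged[k] <- rel == length(in_win)
  }
  out
}

#' @export
print.release_profile <- function(x, ...) {
  cat("Release profile: duration", x$duration, "min, spike half-life",
      x$half_life, "min (gamma =", signif(x$gamma, 4), "/min)\n")
  invisible(x)
}

#' @export
print.spike_train <- function(x, ...) {
  cat("Spike train:", length(x$times), "spikes over",
      signif(max(x$times), 6), "min; amplitudes",
      signif(min(x$amplitudes), 4), "-", signif(max(x$amplitudes), 4),
      "ng/ml/min\n")
  invisible(x)
}

#' @export
print.plasma_signal <- function(x, ...) {
  cat("Plasma signal:", length(x$grid_times), "grid points, step",
      signif(diff(x$grid_times[1:2]), 4), "min;",
      length(x$spike_train$times), "spikes; clearance a =",
      signif(x$a, 4), "/min\n")
  invisible(x)
}
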