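#' Interpulse-interval series of a pulse vector
#'
#' Each interval is the time elapsed between a detected pulse and the
#' previous one, anchored at the later pulse time.
#'
#' @param pulse_times strictly increasing pulse occurrence times, min.
#' @return An object of class `ipi_series`: data frame with `anchor_time`
#'   (min) and `ipi` (min).  Fewer than two pulses give an empty series
#'   with a warning.
#' @examples
#' ipi_series(c(10, 70, 130))   # two intervals of 60 min
#' @export
ipi_series <- function(pulse_times) {
  pulse_times <- as.numeric(pulse_times)
  if (length(pulse_times) >= 2L && any(diff(pulse_times) <= 0))
    stop("'pulse_times' must be strictly increasing")
  if (length(pulse_times) < 2L) {
    warning("fewer than two pulses: empty IPI series")
    return(structure(data.frame(anchor_time = numeric(0), ipi = numeric(0)),
                     class = c("ipi_series", "data.frame")))
  }
  structure(data.frame(anchor_time = pulse_times[-1L],
                       ipi = diff(pulse_times)),
            class = c("ipi_series", "data.frame"))
}

#' Least-squares polynomial trend of an IPI series
#'
#' Fits a cubic polynomial \eqn{\Phi(t)} to the interval durations against
#' their anchor times by ordinary least squares, giving an averaged yet
#' time-evolving representation of the IPI.  With fewer than four intervals
#' the degree is reduced (quadratic / linear / constant for 3 / 2 / 1
#' intervals) so that short series never crash.
#'
#' @param ipis an [ipi_series()] (or data frame with `anchor_time`, `ipi`).
#' @return An object of class `ipi_trend`: list with `coefficients`
#'   (length 4, constant term first, higher orders zero-padded), `degree`
#'   and the fitted `fn(t)`.
#' @export
fit_cubic_trend <- function(ipis) {
  if (nrow(ipis) < 1L) stop("cannot fit a trend to an empty IPI series")
  tt <- ipis$anchor_time
  vv <- ipis$ipi
  deg <- min(3L, nrow(ipis) - 1L)
  coefs <- numeric(4L)
  if (deg == 0L) {
    coefs[1L] <- vv[1L]
  } else {
    fit <- stats::lm(vv ~ stats::poly(tt, degree = deg, raw = TRUE))
    coefs[seq_len(deg + 1L)] <- unname(stats::coef(fit))
  }
  fn <- function(t) coefs[1L] + coefs[2L] * t + coefs[3L] * t^2 +
    coefs[4L] * t^3
  structure(list(coefficients = coefs, degree = deg, fn = fn),
            class = "ipi_trend")
}

#' Build the IPI tunnel around a fitted trend
#'
#' The tunnel is delimited by two piecewise-linear functions of time with
#' knots at the pulse times: the lower edge \eqn{(1-\alpha)\Phi} and the
#' upper edge \eqn{(1+\beta)\Phi}, interpolated linearly between knots and
#' extended as constants beyond the terminal knots.  `alpha` and `beta`
#' quantify the assumed regularity of the pulse frequency.  Knots where the
#' trend dips below zero are floored at zero with a warning.
#'
#' @param trend an [fit_cubic_trend()] result, any function of time, or a
#'   numeric vector of trend values (one per knot).
#' @param pulse_times knot locations, min.
#' @param alpha lower width fraction, in (0, 1).
#' @param beta upper width fraction, positive.
#' @return An object of class `ipi_tunnel`: list with `knots` (data frame
#'   `time`, `phi`, `lower`, `upper`), `alpha`, `beta` and the edge
#'   functions `lower(t)`, `upper(t)`, `phi(t)`.
#' @export
build_tunnel <- function(trend, pulse_times, alpha = 0.6, beta = 0.6) {
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must lie in (0, 1)")
  if (beta <= 0) stop("'beta' must be positive")
  tk <- sort(unique(as.numeric(pulse_times)))
  if (length(tk) < 1L) stop("'pulse_times' must contain at least one knot")
  if (is.numeric(trend)) {
    if (length(trend) != length(tk))
      stop("a numeric 'trend' needs one value per knot")
    phi <- trend
  } else {
    phi_fn <- if (inherits(trend, "ipi_trend")) trend$fn
              else match.fun(trend)
    phi <- phi_fn(tk)
  }
  if (any(phi < 0)) {
    warning("fitted IPI trend is negative at some knots; flooring at 0")
    phi <- pmax(phi, 0)
  }
  knots <- data.frame(time = tk, phi = phi,
                      lower = (1 - alpha) * phi, upper = (1 + beta) * phi)
  edge <- function(vals) {
    if (length(tk) == 1L) {
      v <- vals[1L]
      function(t) rep_len(v, length(t))
    } else {
      function(t) stats::approx(tk, vals, xout = t, rule = 2)$y
    }
  }
  structure(list(knots = knots, alpha = alpha, beta = beta,
                 lower = edge(knots$lower), upper = edge(knots$upper),
                 phi = edge(knots$phi)),
            class = "ipi_tunnel")
}

#' Classify IPI outliers against the tunnel
#'
#' Each interval is compared (strictly) with the interpolated tunnel edges
#' at its anchor time.
#'
#' @param ipis an [ipi_series()].
#' @param tunnel an [build_tunnel()] result computed from the same pulses.
#' @return A factor with levels `below`, `inside`, `above`, one per
#'   interval.
#' @export
classify_outliers <- function(ipis, tunnel) {
  stopifnot(inherits(tunnel, "ipi_tunnel"))
  lo <- tunnel$lower(ipis$anchor_time)
  up <- tunnel$upper(ipis$anchor_time)
  flag <- ifelse(ipis$ipi < lo, "below",
                 ifelse(ipis$ipi > up, "above", "inside"))
  factor(flag, levels = c("below", "inside", "above"))
}

#' Diagnose flagged IPI outliers
#'
#' Annotates each outlier with a suggested interpretation, leaving any
#' correction to the user:
#' \itemize{
#' \item an interval above the tunnel whose duration is about twice the
#'   mean of its neighbouring intervals (ratio within `doubling`), with a
#'   sub-threshold peak present inside it, suggests a \emph{lack of
#'   detection} (one merged interval in place of two);
#' \item an interval above the tunnel without such evidence suggests a
#'   genuine long IPI or a rhythm break, located at the last interval
#'   preceding the outlier;
#' \item an interval below the tunnel suggests an \emph{over-detection};
#'   the weaker of its two flanking pulses is named.
#' }
#'
#' @param ipis an [ipi_series()].
#' @param tunnel the matching [build_tunnel()] result.
#' @param pulse_times pulse occurrence times the intervals derive from.
#' @param series optional series (data frame time/value) used to look for a
#'   sub-threshold peak inside merged intervals; amplitudes of flanking
#'   pulses are also read from it.
#' @param doubling ratio window `c(low, high)` within which an interval is
#'   deemed a doubled one.
#' @return A data frame with one row per interval: `interval`,
#'   `anchor_time`, `ipi`, `flag`, `suggestion`, `detail` and `break_time`
#'   (NA except for rhythm breaks).
#' @export
diagnose_outliers <- function(ipis, tunnel, pulse_times, series = NULL,
                              doubling = c(1.6, 2.4)) {
  flags <- classify_outliers(ipis, tunnel)
  n <- nrow(ipis)
  out <- data.frame(interval = seq_len(n),
                    anchor_time = ipis$anchor_time, ipi = ipis$ipi,
                    flag = as.character(flags),
                    suggestion = "", detail = "", break_time = NA_real_,
                    stringsAsFactors = FALSE)
  if (n == 0L) return(out)
  tt <- yy <- NULL
  if (!is.null(series)) {
    df <- as.data.frame(series)
    tt <- as.numeric(df[[1L]]); yy <- as.numeric(df[[2L]])
  }
  for (k in which(flags != "inside")) {
    left_pulse <- pulse_times[k]       # interval k spans pulses k, k+1
    right_pulse <- pulse_times[k + 1L]
    if (flags[k] == "above") {
      nb <- c(if (k > 1L) ipis$ipi[k - 1L], if (k < n) ipis$ipi[k + 1L])
      ratio <- if (length(nb)) ipis$ipi[k] / mean(nb) else NA_real_
      hidden <- FALSE
      if (!is.null(tt)) {
        inside <- which(tt > left_pulse & tt < right_pulse)
        if (length(inside) >= 3L) {
          cand <- inside[vapply(inside, function(i) is_local_max(yy, i),
                                logical(1))]
          cand <- setdiff(cand, match(c(left_pulse, right_pulse), tt))
          hidden <- length(cand) > 0L
        }
      }
      if (!is.na(ratio) && ratio >= doubling[1L] && ratio <= doubling[2L] &&
          (is.null(tt) || hidden)) {
        out$suggestion[k] <- "possible lack of detection"
        out$detail[k] <- sprintf(
          "interval is %.2f times the mean of its neighbours; %s",
          ratio,
          if (hidden) "a sub-threshold peak lies inside it"
          else "no series supplied to locate the hidden peak")
      } else {
        out$suggestion[k] <- "possible genuine long IPI / rhythm break"
        out$break_time[k] <- if (k > 1L) ipis$anchor_time[k - 1L]
                             else ipis$anchor_time[k]
        out$detail[k] <- sprintf(
          "last in-tunnel interval before the break anchors at %.1f min",
          out$break_time[k])
      }
    } else {  # below
      out$suggestion[k] <- "possible over-detection"
      if (!is.null(tt)) {
        amp <- yy[match(c(left_pulse, right_pulse), tt)]
        weaker <- c(left_pulse, right_pulse)[which.min(amp)]
        out$detail[k] <- sprintf("weaker flanking pulse at %.1f min", weaker)
      } else {
        out$detail[k] <- "weaker flanking pulse undetermined (no series)"
      }
    }
  }
  out
}

#' Trailing-window polynomial trend of an IPI series
#'
#' A causal variant of the IPI trend for rhythm-break monitoring: the
#' trend value at each interval is the one-step-ahead prediction of a
#' polynomial fitted to the intervals of the preceding `window` minutes
#' only.  The fit degree grows with the number of points in the window
#' (mean below 4, linear below 8, quadratic below 12, cubic from 12), so
#' a short history is never extrapolated by a high-order polynomial.
#' A global least-squares cubic accommodates a sustained frequency change
#' at the record end almost perfectly and therefore cannot flag it; the
#' trailing trend keeps tracking the pre-break rhythm, so the first
#' interval of the new regime falls outside the tunnel.
#'
#' @param ipis an [ipi_series()].
#' @param window trailing window length, min.
#' @return Numeric vector of trend values, one per interval (the first
#'   interval, which has no history, is assigned its own value).
#' @export
moving_trend <- function(ipis, window = 400) {
  n <- nrow(ipis)
  phi <- numeric(n)
  for (k in seq_len(n)) {
    tk <- ipis$anchor_time[k]
    sel <- which(ipis$anchor_time < tk & ipis$anchor_time >= tk - window)
    m <- length(sel)
    if (m == 0L) { phi[k] <- ipis$ipi[k]; next }
    deg <- if (m >= 12L) 3L else if (m >= 8L) 2L else if (m >= 4L) 1L else 0L
    if (deg == 0L) {
      phi[k] <- mean(ipis$ipi[sel])
    } else {
      fit <- stats::lm(ipi ~ stats::poly(anchor_time, degree = deg,
                                         raw = TRUE),
                       data = ipis[sel, ])
      co <- c(unname(stats::coef(fit)), rep(0, 3))[1:4]
      phi[k] <- co[1] + co[2] * tk + co[3] * tk^2 + co[4] * tk^3
    }
  }
  phi
}

#' Full IPI-tunnel analysis of a detection result
#'
#' Builds the IPI series of a [detect_pulses()] result, fits the trend,
#' constructs the tunnel and diagnoses outliers.  The default trend is a
#' single global least-squares cubic; `trend = "moving"` uses the
#' trailing-window variant of [moving_trend()], which is the appropriate
#' tool when looking for sudden rhythm breaks.
#'
#' @param detection a `pulse_detection` object.
#' @param alpha,beta tunnel width fractions (see [build_tunnel()]).
#' @param doubling passed to [diagnose_outliers()].
#' @param trend `"global"` or `"moving"`.
#' @param window trailing window of the moving trend, min.
#' @return An object of class `ipi_analysis`: list with `ipis`, `trend`,
#'   `tunnel`, `flags` and the `diagnosis` table.
#' @examples
#' fix <- make_fixture("constant60", seed = 1)
#' det <- detect_pulses(fix$series)
#' an <- ipi_tunnel_analysis(det)
#' table(an$flags)
#' @export
ipi_tunnel_analysis <- function(detection, alpha = 0.6, beta = 0.6,
                                doubling = c(1.6, 2.4),
                                trend = c("global", "moving"),
                                window = 400) {
  stopifnot(inherits(detection, "pulse_detection"))
  trend_kind <- match.arg(trend)
  ipis <- ipi_series(detection$times)
  if (nrow(ipis) == 0L)
    return(structure(list(ipis = ipis, trend = NULL, tunnel = NULL,
                          flags = factor(character(0),
                                         levels = c("below", "inside",
                                                    "above")),
                          diagnosis = NULL),
                     class = "ipi_analysis"))
  if (trend_kind == "global") {
    trend <- fit_cubic_trend(ipis)
    tunnel <- build_tunnel(trend, detection$times, alpha = alpha,
                           beta = beta)
  } else {
    trend <- moving_trend(ipis, window = window)
    tunnel <- build_tunnel(trend, ipis$anchor_time, alpha = alpha,
                           beta = beta)
  }
  flags <- classify_outliers(ipis, tunnel)
  diagnosis <- diagnose_outliers(ipis, tunnel, detection$times,
                                 series = detection$series,
                                 doubling = doubling)
  structure(list(ipis = ipis, trend = trend, tunnel = tunnel,
                 flags = flags, diagnosis = diagnosis),
            class = "ipi_analysis")
}

#' @export
print.ipi_analysis <- function(x, ...) {
  n <- nrow(x$ipis)
  cat("IPI analysis:", n, "intervals")
  if (n) {
    cat("; mean IPI", signif(mean(x$ipis$ipi), 4), "min;",
        sum(x$flags != "inside"), "outlier(s)\n")
    out <- x$diagnosis[x$diagnosis$flag != "inside", , drop = FALSE]
    if (nrow(out))
      for (k in seq_len(nrow(out)))
        cat(sprintf("  t = %.1f min, IPI = %.1f min [%s]: %s\n",
                    out$anchor_time[k], out$ipi[k], out$flag[k],
                    out$suggestion[k]))
  } else cat("\n")
  invisible(x)
}
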