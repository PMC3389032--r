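#' Pulse-detection configuration
#'
#' Tunable parameters of the multiscale pulse-selection process.
#'
#' @param Ts sampling period of the series, min.
#' @param Tp nominal period, min: the shortest delay within which, from one
#'   pulse occurrence, the next one is expected.  Sizes the forward-search
#'   windows; must be at least `2 * Ts`.
#' @param lambda_r relative magnitude threshold in (0, 1); peaks whose
#'   height (or magnitude) falls below this fraction of the reference are
#'   removed.
#' @param lambda_a absolute magnitude threshold, ng/ml; corresponds to the
#'   assay detection threshold (default 0 for synthetic data).
#' @param lambda_3p 3-point peak sharpness threshold in (0, 1).
#' @return An object of class `detection_config`.
#' @export
detection_config <- function(Ts, Tp = 40, lambda_r = 0.2, lambda_a = 0,
                             lambda_3p = 0.1) {
  if (Ts <= 0) stop("'Ts' must be positive")
  if (Tp < 2 * Ts) stop("'Tp' must be at least twice the sampling period")
  if (lambda_r <= 0 || lambda_r >= 1) stop("'lambda_r' must lie in (0, 1)")
  if (lambda_a < 0) stop("'lambda_a' must be non-negative")
  if (lambda_3p <= 0 || lambda_3p >= 1) stop("'lambda_3p' must lie in (0, 1)")
  structure(list(Ts = Ts, Tp = Tp, lambda_r = lambda_r,
                 lambda_a = lambda_a, lambda_3p = lambda_3p),
            class = "detection_config")
}

#' Height of a sample above the series minimum
#'
#' The height of the peak at index `i` is its amplitude minus the lowest
#' value of the whole series — a normalisation that is invariant under
#' adding a constant to every sample.
#'
#' @param y numeric vector of measured levels.
#' @param i sample index (1-based).
#' @return Height in the units of `y`.
#' @export
pulse_height <- function(y, i) y[i] - min(y)

## Nearest flanking pulse indices of i in P; the series boundaries stand in
## when a flank is missing (first/last pulse).
flanks <- function(P, i, N) {
  prev <- P[P < i]
  nxt <- P[P > i]
  c(if (length(prev)) max(prev) else 1L,
    if (length(nxt)) min(nxt) else N)
}

#' Magnitude of a peak relative to its flanking pulses
#'
#' Let `U` be the peak amplitude minus the minimal value of the series
#' between the previous pulse registered in `P` and the peak, and `V` the
#' same on the right side.  The magnitude is the geometric mean
#' \eqn{\sqrt{UV}}: it accounts for the local baseline while remaining
#' insensitive to a baseline difference between the two sides.  A peak not
#' rising above one of its local minima (`U` or `V` zero) has magnitude 0.
#' For the first/last pulse the series start/end bounds the missing side.
#'
#' @param y numeric vector of measured levels.
#' @param P strictly increasing integer vector of current pulse indices.
#' @param i index of the peak under examination.
#' @return Magnitude, same units as `y`.
#' @export
pulse_magnitude <- function(y, P, i) {
  fl <- flanks(P, i, length(y))
  U <- y[i] - min(y[fl[1L]:i])
  V <- y[i] - min(y[i:fl[2L]])
  if (U <= 0 || V <= 0) 0 else sqrt(U * V)
}

#' Relative magnitude between two peaks
#'
#' Geometric mean of the two peaks' elevations above the minimal value of
#' the series between them; 0 when either peak does not rise above that
#' minimum.  Symmetric in its arguments.
#'
#' @param y numeric vector of measured levels.
#' @param i,j indices of the two peaks.
#' @return Relative magnitude, same units as `y`.
#' @export
relative_magnitude <- function(y, i, j) {
  lo <- min(i, j); hi <- max(i, j)
  m <- min(y[lo:hi])
  u <- y[lo] - m; v <- y[hi] - m
  if (u <= 0 || v <= 0) 0 else sqrt(u * v)
}

is_local_max <- function(y, i) {
  N <- length(y)
  left <- i == 1L || y[i] >= y[i - 1L]
  right <- i == N || y[i] >= y[i + 1L]
  left && right
}

## Interior local maxima of y on index range (from, to), both exclusive.
interior_maxima <- function(y, from, to) {
  if (to - from < 2L) return(integer(0))
  idx <- (from + 1L):(to - 1L)
  idx[vapply(idx, function(i) is_local_max(y, i), logical(1))]
}

#' Initial forward search for candidate pulses
#'
#' Seeds the pulse vector by alternating windowed extrema: the first
#' candidate is the maximal sample over the first `2 * Tp` of the record;
#' then, repeatedly, the minimal sample among the `kp = round(Tp/Ts)`
#' samples directly following the current candidate is located, and the
#' maximal sample among the `kp` samples directly following that minimum
#' becomes the next candidate, until the series end.  Ties keep the
#' earliest index.  Candidates landing on a shoulder are snapped to the
#' nearest local maximum within one sample.
#'
#' @param y numeric vector of measured levels.
#' @param Ts sampling period, min.
#' @param Tp nominal period, min.
#' @return Strictly increasing integer vector of candidate pulse indices.
#' @export
initialize_pulses <- function(y, Ts, Tp) {
  N <- length(y)
  kp <- max(1L, as.integer(round(Tp / Ts)))
  win0 <- as.integer(ceiling(2 * Tp / Ts))
  if (N <= win0)
    stop("series shorter than twice the nominal period; cannot initialize")
  k <- which.max(y[seq_len(win0)])
  P <- k
  repeat {
    # near the record end the windows may be truncated, but a minimum
    # window spanning less than half the nominal period no longer probes a
    # meaningful range and would only promote tail noise to a candidate
    if (N - k < ceiling(kp / 2)) break
    mwin <- seq.int(k + 1L, min(k + kp, N))
    m <- mwin[which.min(y[mwin])]
    if (m + 1L > N) break
    awin <- seq.int(m + 1L, min(m + kp, N))
    k <- awin[which.max(y[awin])]
    P <- c(P, k)
  }
  P <- vapply(P, function(i) snap_to_local_max(y, i), integer(1))
  sort(unique(P))
}

snap_to_local_max <- function(y, i) {
  if (is_local_max(y, i)) return(as.integer(i))
  N <- length(y)
  cand <- c(i - 1L, i + 1L)
  cand <- cand[cand >= 1L & cand <= N]
  cand <- cand[vapply(cand, function(j) is_local_max(y, j), logical(1))]
  if (length(cand) == 0L) return(as.integer(i))
  as.integer(cand[which.max(y[cand])])
}

#' Global relative criterion
#'
#' Removes, in a single pass, every pulse whose height is less than
#' `lambda_r` times the median height of the incoming pulse set.  The
#' median (rather than a mean) keeps the reference insensitive to a few
#' very tall peaks.
#'
#' @inheritParams pulse_magnitude
#' @param lambda_r relative threshold in (0, 1).
#' @return The filtered pulse index vector.
#' @export
apply_global_relative <- function(y, P, lambda_r) {
  if (length(P) == 0L) return(P)
  h <- y[P] - min(y)
  med <- stats::median(h)
  if (!is.finite(med) || med <= 0) return(P)
  P[!(h / med < lambda_r)]
}

#' Semi-local relative criterion
#'
#' Compares each interior pulse's magnitude with the relative magnitude
#' between its immediately preceding and following pulses; a pulse is
#' removed when its magnitude is strictly below `lambda_r` times that
#' reference.  Because a removal changes the flanks of the neighbouring
#' pulses, left-to-right passes are repeated until no pulse is removed.
#'
#' @inheritParams apply_global_relative
#' @return The filtered pulse index vector.
#' @export
apply_semilocal <- function(y, P, lambda_r) {
  repeat {
    if (length(P) < 3L) return(P)
    removed <- FALSE
    j <- 2L
    while (j <= length(P) - 1L) {
      mag <- pulse_magnitude(y, P, P[j])
      ref <- relative_magnitude(y, P[j - 1L], P[j + 1L])
      if (mag < lambda_r * ref) {
        P <- P[-j]
        removed <- TRUE
      } else {
        j <- j + 1L
      }
    }
    if (!removed) return(P)
  }
}

#' Global absolute criterion
#'
#' Removes pulses whose magnitude, recomputed against the current pulse set
#' before each test, falls strictly below the assay detection threshold
#' `lambda_a`.  This precludes insignificant elevations of the baseline
#' from being kept as pulses.
#'
#' @inheritParams pulse_magnitude
#' @param lambda_a absolute threshold, ng/ml.
#' @return The filtered pulse index vector.
#' @export
apply_global_absolute <- function(y, P, lambda_a) {
  if (lambda_a < 0) stop("'lambda_a' must be non-negative")
  if (lambda_a == 0) return(P)
  j <- 1L
  while (j <= length(P)) {
    if (pulse_magnitude(y, P, P[j]) < lambda_a) P <- P[-j] else j <- j + 1L
  }
  P
}

#' Retrieve missed pulses
#'
#' Examines, between each pair of successive pulses, the interior local
#' maxima in decreasing amplitude order; a candidate is added to the pulse
#' vector when it clears the semi-local threshold on both sides: each of
#' its elevations above the minima separating it from the gap ends must
#' reach `lambda_r` times the relative magnitude between the flanking
#' pulses (which implies the same bound for its magnitude, their geometric
#' mean).  Requiring both sides — rather than the geometric mean alone —
#' keeps a peak sitting on the rising or falling flank of an existing
#' pulse, whose inner elevation is only assay-noise deep while its outer
#' elevation spans the whole gap, from being promoted to a pulse.  After
#' an addition the gap is split in two and each half is re-examined.
#' A candidate closer than `min_sep` samples to either flanking pulse is
#' part of the same secretory event and is never added; [detect_pulses()]
#' sets this to half the nominal period.
#'
#' The head segment before the first pulse and the tail segment after the
#' last one are examined too, with the record boundary standing in for the
#' missing flank and the relative magnitude of the nearest genuine pulse
#' pair as the reference: the forward search can otherwise strand a
#' genuine first pulse behind its own initial window.
#'
#' @inheritParams apply_global_relative
#' @param min_sep minimal separation, in samples, between an added pulse
#'   and its flanking pulses (0 disables the guard).
#' @return The augmented pulse index vector.
#' @export
retrieve_missed <- function(y, P, lambda_r, min_sep = 0L) {
  if (length(P) < 2L) return(P)
  N <- length(y)
  added <- integer(0)
  accept <- function(cc, lo, hi, ref) {
    U <- y[cc] - min(y[lo:cc])
    V <- y[cc] - min(y[cc:hi])
    ref > 0 && min(U, V) >= lambda_r * ref
  }
  examine <- function(p, q) {
    cand <- interior_maxima(y, p, q)
    cand <- cand[cand - p >= min_sep & q - cand >= min_sep]
    if (length(cand) == 0L) return(invisible())
    cand <- cand[order(y[cand], decreasing = TRUE)]
    ref <- relative_magnitude(y, p, q)
    for (cc in cand) {
      if (accept(cc, p, q, ref)) {
        added <<- c(added, cc)
        examine(p, cc)
        examine(cc, q)
        return(invisible())
      }
    }
    invisible()
  }
  examine_edge <- function(bound, flank, ref, head) {
    cand <- if (head) interior_maxima(y, 0L, flank)
            else interior_maxima(y, flank, N + 1L)
    cand <- cand[abs(cand - flank) >= min_sep]
    if (length(cand) == 0L) return(invisible())
    cand <- cand[order(y[cand], decreasing = TRUE)]
    for (cc in cand) {
      if (accept(cc, if (head) 1L else flank, if (head) flank else N, ref)) {
        added <<- c(added, cc)
        if (head) {
          examine_edge(bound, cc, ref, head = TRUE)
          examine(cc, flank)
        } else {
          examine(flank, cc)
          examine_edge(bound, cc, ref, head = FALSE)
        }
        return(invisible())
      }
    }
    invisible()
  }
  for (g in seq_len(length(P) - 1L)) examine(P[g], P[g + 1L])
  n <- length(P)
  examine_edge(1L, P[1L], relative_magnitude(y, P[1L], P[2L]), head = TRUE)
  examine_edge(N, P[n], relative_magnitude(y, P[n - 1L], P[n]), head = FALSE)
  sort(unique(c(P, added)))
}

#' Sharpness coefficient of a 3-point peak
#'
#' For a peak whose two immediate neighbours are local minima, the
#' coefficient is the arithmetic mean of the rank-2 rebounds
#' (`y[i-2] - y[i-1]` and `y[i+2] - y[i+1]`, each floored at 0: a point
#' that continues the decay contributes nothing) divided by the geometric
#' mean of the peak's elevations above the minima separating it from its
#' flanking pulses (its magnitude; the series boundaries stand in when `P`
#' is not supplied).  For the canonical sharp artefact — a peak whose
#' immediate neighbours are themselves the minima toward the flanks — the
#' denominator reduces to the geometric mean of the two immediate drops,
#' and the rebounds are commensurate with it, giving a coefficient of
#' order one.  A genuine pulse summit jagged only by assay noise rebounds
#' on the noise scale, far below its own magnitude, and scores near 0.
#' Peaks too close to the series edge for the rank-2 neighbours to exist
#' score 0 (never removed).
#'
#' @param y numeric vector of measured levels.
#' @param i peak index.
#' @param P optional pulse index vector providing the flanks for the
#'   magnitude in the denominator.
#' @param rank neighbour spacing in samples.  Rank 1 (the default) probes
#'   the immediate and rank-2 neighbours, which at a 10-min protocol spans
#'   the typical pulse duration; at finer sampling the rank is scaled up
#'   (see [remove_3point_peaks()]) so that the probe stays at the
#'   duration scale instead of the sample scale.
#' @return Dimensionless sharpness coefficient (0 when undefined).
#' @examples
#' sharpness_coefficient(c(1.0, 0.2, 2.0, 0.3, 1.1), 3)   # 0.457...
#' @export
sharpness_coefficient <- function(y, i, P = NULL, rank = 1L) {
  N <- length(y)
  r <- as.integer(rank)
  if (i - 2L * r < 1L || i + 2L * r > N) return(0)
  if (y[i] <= y[i - r] || y[i] <= y[i + r]) return(0)
  if (is.null(P)) P <- as.integer(i)
  denom <- pulse_magnitude(y, P, i)
  if (denom <= 0) return(0)
  rebound <- c(max(y[i - 2L * r] - y[i - r], 0),
               max(y[i + 2L * r] - y[i + r], 0))
  mean(rebound) / denom
}

is_three_point_peak <- function(y, i, rank = 1L) {
  N <- length(y)
  r <- as.integer(rank)
  if (i - 2L * r < 1L || i + 2L * r > N) return(FALSE)
  y[i - 2L * r] > y[i - r] && y[i - r] < y[i] &&
    y[i + r] < y[i] && y[i + r] < y[i + 2L * r]
}

#' Remove overly sharp 3-point peaks
#'
#' A pulse whose neighbouring samples at the probe rank are both local
#' minima extends over too short a duration; such a pattern is incompatible
#' with the asymmetric, multi-sample shape of a genuine pulse unless it is
#' merely a noised pulse summit.  Pulses matching the pattern with a
#' sharpness coefficient strictly greater than `lambda_3p` are removed.
#' The probe rank defaults to 1 (immediate neighbours); passing the
#' nominal period scales it to `round(Tp / (4 Ts))` samples so that the
#' criterion keeps testing the same span of minutes around the summit
#' whatever the sampling period.
#'
#' @inheritParams pulse_magnitude
#' @param lambda_3p sharpness threshold.
#' @param rank neighbour spacing in samples (see [sharpness_coefficient()]).
#' @return The filtered pulse index vector.
#' @export
remove_3point_peaks <- function(y, P, lambda_3p, rank = 1L) {
  if (length(P) == 0L) return(P)
  drop <- vapply(P, function(i)
    is_three_point_peak(y, i, rank) &&
      sharpness_coefficient(y, i, P, rank) > lambda_3p,
    logical(1))
  P[!drop]
}

#' Detect pulses in a sampled hormonal series
#'
#' Runs the full selection pipeline: forward-search initialisation, global
#' relative criterion, semi-local relative criterion, global absolute
#' criterion, retrieval of missed pulses, and 3-point peak removal, in that
#' order.  Deterministic for a fixed series and configuration.
#'
#' @param series a `sampled_series` or a data frame whose first two columns
#'   are time (min) and measured level (ng/ml).
#' @param config a [detection_config()]; when `NULL`, defaults are used
#'   with `Ts` taken from the series attribute or the median time gap.
#' @return An object of class `pulse_detection`: list with `pulses`
#'   (1-based sample indices), `times`, `amplitudes`, `series`, `config`
#'   and `stages` (the pulse vector after every stage).
#' @examples
#' fix <- make_fixture("constant60", seed = 1)
#' det <- detect_pulses(fix$series)
#' det$times
#' @export
detect_pulses <- function(series, config = NULL) {
  df <- as.data.frame(series)
  if (ncol(df) < 2L) stop("'series' needs time and value columns")
  tt <- as.numeric(df[[1L]])
  y <- as.numeric(df[[2L]])
  if (anyNA(tt) || anyNA(y)) stop("'series' contains missing values")
  if (is.null(config)) {
    Ts <- attr(series, "Ts")
    if (is.null(Ts)) Ts <- stats::median(diff(tt))
    config <- detection_config(Ts = Ts)
  }
  stopifnot(inherits(config, "detection_config"))
  stages <- list()
  P <- initialize_pulses(y, config$Ts, config$Tp)
  stages$initialize <- P
  P <- apply_global_relative(y, P, config$lambda_r)
  stages$global_relative <- P
  P <- apply_semilocal(y, P, config$lambda_r)
  stages$semilocal <- P
  P <- apply_global_absolute(y, P, config$lambda_a)
  stages$global_absolute <- P
  P <- retrieve_missed(y, P, config$lambda_r,
                       min_sep = round(config$Tp / (2 * config$Ts)))
  stages$retrieve_missed <- P
  P <- remove_3point_peaks(y, P, config$lambda_3p,
                           rank = max(1L, round(config$Tp / (4 * config$Ts))))
  stages$three_point <- P
  if (length(P) == 0L) warning("no pulse survived the selection process")
  structure(list(pulses = P, times = tt[P], amplitudes = y[P],
                 series = df, config = config, stages = stages),
            class = "pulse_detection")
}

#' @export
print.pulse_detection <- function(x, ...) {
  cat("Pulse detection:", length(x$pulses), "pulses over",
      signif(diff(range(x$series[[1L]])), 6), "min\n")
  if (length(x$pulses)) {
    ipi <- diff(x$times)
    cat("  occurrences (min):", paste(signif(x$times, 6), collapse = ", "),
        "\n")
    if (length(ipi))
      cat("  IPI range:", signif(min(ipi), 4), "-", signif(max(ipi), 4),
          "min\n")
  }
  invisible(x)
}
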