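#' Named synthetic scenarios with ground truth
#'
#' Regenerates, from a seed, the benchmark scenarios used throughout the
#' package together with the ground-truth spike and theoretical pulse
#' times needed to score a detection:
#' \describe{
#' \item{`constant60`}{constant amplitude, one spike per hour, 1000 min,
#'   noise-free 10-min sampling: the textbook regular series.}
#' \item{`case_a` .. `case_d`}{constant amplitude and 60-min interspike
#'   interval sampled at 10 min with, respectively, a 1-min offset and no
#'   noise; a 4-min offset; added time jitter (`f` = 1.5 min); added assay
#'   noise (`b` = 10\%).}
#' \item{`case_e`}{constant amplitude, interspike interval ramping from
#'   100 to 50 min, noise-free 10-min sampling from minute 1.}
#' \item{`case_f`}{amplitude ramping down (15 to 6.5 ng/ml/min) together
#'   with the interval ramp 100 to 50 min; 4-min offset, 2-min jitter, 5\%
#'   assay noise.}
#' \item{`s4_ramp`}{amplitude 15 to 6.5 ng/ml/min and interspike interval
#'   80 to 50 min over 1000 min; jitter 15\% of `ts`, assay noise `b`
#'   (default 0).}
#' \item{`fig7`}{the same ramp sampled with `b` = 5\% and jitter 15\% of
#'   `ts`, for studying invariance of the detected count across sampling
#'   periods `ts` of 1, 5 or 10 min.}
#' }
#'
#' @param name scenario name (see Details).
#' @param seed master seed for jitter and assay noise.
#' @param ts sampling period, min.
#' @param b assay-noise fraction override (scenarios with fixed noise
#'   ignore it).
#' @param noise_dist `"uniform"` or `"normal"` assay-error distribution.
#' @param signal optionally, a precomputed `plasma_signal` for this
#'   scenario (as returned in a previous call) to skip re-integration when
#'   sampling many replicates of the same truth.
#' @return A list with `series` (a `sampled_series`), `truth` (the
#'   [theoretical_pulses()] table), `signal` and `profile`.
#' @export
make_fixture <- function(name, seed = 1, ts = 10, b = NULL,
                         noise_dist = "uniform", signal = NULL) {
  specs <- list(
    constant60 = list(amplitude = 1, ipi = 60, r = 1, f = 0, b = 0),
    case_a = list(amplitude = 1, ipi = 60, r = 1, f = 0, b = 0),
    case_b = list(amplitude = 1, ipi = 60, r = 4, f = 0, b = 0),
    case_c = list(amplitude = 1, ipi = 60, r = 4, f = 1.5, b = 0),
    case_d = list(amplitude = 1, ipi = 60, r = 4, f = 1.5, b = 0.10),
    case_e = list(amplitude = 1, ipi = c(100, 50), r = 1, f = 0, b = 0),
    case_f = list(amplitude = c(15, 6.5), ipi = c(100, 50), r = 4, f = 2,
                  b = 0.05),
    s4_ramp = list(amplitude = c(15, 6.5), ipi = c(80, 50), r = 1,
                   f = NA, b = 0),
    fig7 = list(amplitude = c(15, 6.5), ipi = c(80, 50), r = 1,
                f = NA, b = 0.05))
  if (!name %in% names(specs))
    stop("unknown fixture '", name, "'; available: ",
         paste(names(specs), collapse = ", "))
  sp <- specs[[name]]
  duration <- 1000
  if (is.na(sp$f)) sp$f <- 0.15 * ts          # jitter tied to the period
  if (!is.null(b)) sp$b <- b
  profile <- release_profile(sp$amplitude, sp$ipi, half_life = 2,
                             duration = duration)
  if (is.null(signal)) signal <- simulate_plasma(profile)
  N <- floor((duration - sp$r - sp$f) / ts) + 1
  cfg <- sampling_config(Ts = ts, N = N, r = sp$r, f = sp$f, b = sp$b,
                         seed = seed, noise_dist = noise_dist)
  list(series = sample_series(signal, cfg),
       truth = theoretical_pulses(signal),
       signal = signal, profile = profile)
}

#' Score a detection against ground truth
#'
#' Matches each detected occurrence to the nearest true pulse time.  A true
#' pulse claimed by no detection is a miss (lack of detection); a true
#' pulse claimed more than once, or a detection farther from every true
#' pulse than half the smallest true interpulse interval, counts as an
#' over-detection.  A series is scored accurate when both counts are zero.
#'
#' @param detected_times detected pulse occurrence times, min.
#' @param truth_times theoretical pulse times, min.
#' @return A list with `missed`, `over`, `accurate` and the assignment
#'   vector `match` (index of the true pulse claimed by each detection).
#' @export
score_detection <- function(detected_times, truth_times) {
  if (length(truth_times) == 0L) stop("'truth_times' is empty")
  half_gap <- if (length(truth_times) > 1L) min(diff(truth_times)) / 2 else Inf
  match_idx <- integer(0)
  over <- 0L
  if (length(detected_times)) {
    match_idx <- vapply(detected_times, function(d)
      which.min(abs(truth_times - d)), integer(1))
    dist <- abs(truth_times[match_idx] - detected_times)
    stray <- dist > half_gap
    over <- sum(stray)
    claimed <- table(match_idx[!stray])
    over <- over + sum(pmax(claimed - 1L, 0L))
    missed <- length(truth_times) - sum(claimed >= 1L)
  } else {
    missed <- length(truth_times)
  }
  list(missed = as.integer(missed), over = as.integer(over),
       accurate = missed == 0L && over == 0L, match = match_idx)
}

#' Noise-robustness sweep of the detection algorithm
#'
#' Replicates the assay-error robustness design: from one theoretical
#' signal (the `s4_ramp` scenario), several series are sampled per noise
#' level and the detection outcome of each is scored into three mutually
#' exclusive classes — accurate, erroneous with at least one IPI-tunnel
#' outlier, or erroneous without any outlier.  The same jitter and base
#' noise draws are reused across noise levels (common random numbers), so
#' the levels differ only by the amplitude of the assay error.
#'
#' @param b_levels assay-noise fractions to sweep.
#' @param n_series number of replicate series per level.
#' @param seed master seed; replicate `j` uses a seed derived from it and
#'   from `j` alone.
#' @param ts sampling period, min.
#' @param noise_dist `"uniform"` or `"normal"`.
#' @return A list with `runs` (data frame: `b`, `series`, `missed`, `over`,
#'   `accurate`, `outlier_flagged`, `class`) and `summary` (per-level
#'   accuracy and class tallies).
#' @export
noise_sweep <- function(b_levels = c(0.08, 0.16, 0.24, 0.32, 0.38, 0.44),
                        n_series = 10, seed = 1, ts = 10,
                        noise_dist = "uniform") {
  base <- make_fixture("s4_ramp", seed = seed, ts = ts, b = 0)
  runs <- do.call(rbind, lapply(seq_len(n_series), function(j) {
    sj <- derive_seed(seed, 100L + j)
    do.call(rbind, lapply(b_levels, function(b) {
      fix <- make_fixture("s4_ramp", seed = sj, ts = ts, b = b,
                          noise_dist = noise_dist, signal = base$signal)
      det <- detect_pulses(fix$series,
                           detection_config(Ts = ts))
      sc <- score_detection(det$times, fix$truth$pulse_time)
      an <- ipi_tunnel_analysis(det)
      flagged <- any(an$flags != "inside")
      data.frame(b = b, series = j, missed = sc$missed, over = sc$over,
                 accurate = sc$accurate, outlier_flagged = flagged,
                 class = if (sc$accurate) "accurate"
                         else if (flagged) "error_with_outlier"
                         else "error_silent",
                 stringsAsFactors = FALSE)
    }))
  }))
  summary <- do.call(rbind, lapply(split(runs, runs$b), function(d)
    data.frame(b = d$b[1L], accuracy = mean(d$accurate),
               accurate = sum(d$class == "accurate"),
               error_with_outlier = sum(d$class == "error_with_outlier"),
               error_silent = sum(d$class == "error_silent"))))
  rownames(summary) <- NULL
  list(runs = runs, summary = summary[order(summary$b), ])
}
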