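#' Sampling protocol configuration
#'
#' Parameters of the synthetic blood-sampling protocol: samples are drawn
#' every `Ts` minutes starting at `r`, the actual draw time is jittered
#' uniformly within `[-f, +f]` of the nominal time, and the assayed value
#' carries a multiplicative uniform error of relative amplitude `b`.
#'
#' @param Ts sampling period, min.
#' @param N number of samples.
#' @param r first-sample offset, min, in `[0, Ts]`.
#' @param f maximal time jitter, min; must satisfy `f < Ts/2` so that
#'   consecutive samples cannot be drawn in inverted order.
#' @param b assay-noise fraction in `[0, 1)`.
#' @param seed master RNG seed; spawns independent substreams for jitter and
#'   assay noise so that switching one off leaves the other's draws intact.
#' @param noise_dist `"uniform"` (default) or `"normal"`; the normal variant
#'   uses `b` as the relative standard deviation and truncates negative
#'   measured values at zero.
#' @return An object of class `sampling_config`.
#' @export
sampling_config <- function(Ts, N, r = 1, f = 0, b = 0, seed = NULL,
                            noise_dist = c("uniform", "normal")) {
  noise_dist <- match.arg(noise_dist)
  if (Ts <= 0) stop("'Ts' must be positive")
  if (N < 1) stop("'N' must be at least 1")
  if (r < 0 || r > Ts) stop("'r' must lie in [0, Ts]")
  if (f < 0 || f >= Ts / 2)
    stop("'f' must lie in [0, Ts/2): larger jitter could invert sample order")
  if (b < 0 || (noise_dist == "uniform" && b >= 1))
    stop("'b' must lie in [0, 1)")
  structure(list(Ts = Ts, N = as.integer(N), r = r, f = f, b = b,
                 seed = seed, noise_dist = noise_dist),
            class = "sampling_config")
}

#' Nominal sampling times
#'
#' @param Ts sampling period, min.
#' @param r first-sample offset, min.
#' @param N number of samples.
#' @return The vector \eqn{t_i = r + (i-1) Ts}, `i = 1..N`.
#' @examples
#' nominal_times(10, 1, 3)   # 1, 11, 21
#' @export
nominal_times <- function(Ts, r, N) {
  if (Ts <= 0 || N < 1) stop("'Ts' must be positive and 'N' at least 1")
  r + (seq_len(N) - 1) * Ts
}

## Evaluate `code` under a Mersenne-Twister stream seeded with `seed`,
## restoring the caller's RNG state afterwards.  NULL seed leaves the
## global stream untouched.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed, kind = "Mersenne-Twister")
  }
  code
}

## Derive a substream seed below 2^31 from a master seed and a stream id.
derive_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + stream * 104729) %% 2147483629)
}

#' Jitter nominal sampling times
#'
#' Each effective time is drawn independently and uniformly from
#' `[t - f, t + f]`.
#'
#' @param times nominal times, min.
#' @param f maximal jitter, min; must be smaller than half the smallest gap
#'   between nominal times.
#' @param seed optional seed for a private RNG stream.
#' @return Effective times, same length as `times`.
#' @export
jitter_times <- function(times, f, seed = NULL) {
  if (f < 0) stop("'f' must be non-negative")
  if (f == 0) return(times)
  if (length(times) > 1L && f >= min(diff(times)) / 2)
    stop("'f' must be less than half the sampling period ",
         "(sample order could invert)")
  with_seed(seed, times + stats::runif(length(times), -f, f))
}

#' Apply multiplicative assay noise
#'
#' Models assay variance as \eqn{y_i = x_i (1 + \epsilon_i)} with
#' \eqn{\epsilon_i} uniform on `[-b, b]` (or, with `dist = "normal"`,
#' Gaussian with standard deviation `b`, measured values truncated at 0).
#'
#' @param values true levels, ng/ml.
#' @param b relative noise amplitude (uniform half-width or normal SD).
#' @param seed optional seed for a private RNG stream.
#' @param dist `"uniform"` or `"normal"`.
#' @return Noisy measured values.
#' @export
assay_noise <- function(values, b, seed = NULL,
                        dist = c("uniform", "normal")) {
  dist <- match.arg(dist)
  if (b < 0) stop("'b' must be non-negative")
  if (b == 0) return(values)
  with_seed(seed, {
    eps <- switch(dist,
                  uniform = stats::runif(length(values), -b, b),
                  normal  = stats::rnorm(length(values), 0, b))
    pmax(values * (1 + eps), 0)
  })
}

#' Sample a plasma signal through the noisy protocol
#'
#' Composes the protocol stages: nominal times, uniform time jitter,
#' evaluation of the plasma level at the effective times (linear
#' interpolation on the fine grid), and multiplicative assay noise.  Fully
#' reproducible from the configuration seed; jitter and noise use
#' independent substreams.
#'
#' @param signal a `plasma_signal` (see [integrate_plasma()]).
#' @param cfg a [sampling_config()].
#' @return A `sampled_series`: a data frame with columns `time` (nominal
#'   sampling time, min), `value` (measured level, ng/ml) and
#'   `effective_time` (actual draw time, known in simulation only), with
#'   attributes `Ts` and `config`.
#' @export
sample_series <- function(signal, cfg) {
  stopifnot(inherits(signal, "plasma_signal"), inherits(cfg, "sampling_config"))
  duration <- max(signal$grid_times)
  if (cfg$r + (cfg$N - 1) * cfg$Ts + cfg$f > duration)
    stop("requested sampling window exceeds the simulated signal duration")
  nom <- nominal_times(cfg$Ts, cfg$r, cfg$N)
  eff <- jitter_times(nom, cfg$f, seed = derive_seed(cfg$seed, 1L))
  # a jittered first sample can precede t = 0 when r < f; the level there
  # is the pre-record initial level (constant extension of the grid)
  true <- stats::approx(signal$grid_times, signal$levels, xout = eff,
                        rule = 2)$y
  val <- assay_noise(true, cfg$b, seed = derive_seed(cfg$seed, 2L),
                     dist = cfg$noise_dist)
  as_sampled_series(data.frame(time = nom, value = val,
                               effective_time = eff),
                    Ts = cfg$Ts, config = cfg)
}

as_sampled_series <- function(df, Ts, config = NULL) {
  structure(df, Ts = Ts, config = config,
            class = c("sampled_series", "data.frame"))
}

#' @export
print.sampled_series <- function(x, ...) {
  cat("Sampled series:", nrow(x), "samples, Ts =", attr(x, "Ts"),
      "min, levels", signif(min(x$value), 4), "-", signif(max(x$value), 4),
      "ng/ml\n")
  invisible(x)
}
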