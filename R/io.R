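#' Read a sampled hormonal series from delimited text
#'
#' Accepts CSV or TSV (delimiter sniffed among comma, semicolon and tab)
#' with or without a header row; the first two numeric columns are taken
#' as sampling time (min) and measured level (ng/ml).  The sampling period
#' is inferred as the median time gap; irregular spacing (gaps deviating
#' more than 20\% from it) draws a warning.
#'
#' @param path path to the file.
#' @param sep optional delimiter override.
#' @return A `sampled_series` with attribute `Ts`.
#' @export
read_series <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("input file is empty: ", path)
  if (is.null(sep)) {
    counts <- vapply(c(",", ";", "\t"), function(s)
      lengths(regmatches(first, gregexpr(s, first, fixed = TRUE))),
      integer(1))
    sep <- if (max(counts) == 0L) "," else c(",", ";", "\t")[which.max(counts)]
  }
  probe <- strsplit(first, sep, fixed = TRUE)[[1L]]
  header <- anyNA(suppressWarnings(as.numeric(probe[1:min(2, length(probe))])))
  df <- utils::read.table(path, sep = sep, header = header,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop("expected at least two columns (time, level) in ", path)
  tt <- suppressWarnings(as.numeric(df[[1L]]))
  yy <- suppressWarnings(as.numeric(df[[2L]]))
  bad <- which(!is.finite(tt) | !is.finite(yy))
  if (length(bad))
    stop("non-numeric cell(s) at data line ", bad[1L], " of ", path)
  if (length(tt) < 10L)
    stop("series too short (", length(tt), " samples; need at least 10)")
  dup <- which(diff(tt) == 0)
  if (length(dup))
    stop("duplicated timestamp at data line ", dup[1L] + 1L, " of ", path)
  if (any(diff(tt) < 0))
    stop("sampling times must be strictly increasing in ", path)
  gaps <- diff(tt)
  Ts <- stats::median(gaps)
  if (any(abs(gaps - Ts) / Ts > 0.2))
    warning("sampling gaps vary by more than 20% around the median (",
            signif(Ts, 4), " min)")
  out <- data.frame(time = tt, value = yy)
  if (ncol(df) >= 3L) {
    eff <- suppressWarnings(as.numeric(df[[3L]]))
    if (all(is.finite(eff))) out$effective_time <- eff
  }
  as_sampled_series(out, Ts = Ts)
}

#' Write a sampled series as CSV
#'
#' Columns `time_min` and `lh_ng_per_ml`, plus `effective_time_min` when
#' the series carries simulated effective draw times.  Values are written
#' with enough digits for a lossless round trip at six significant digits.
#'
#' @param series a `sampled_series` or two-column data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  df <- as.data.frame(series)
  out <- data.frame(time_min = df[[1L]], lh_ng_per_ml = df[[2L]])
  if ("effective_time" %in% names(df))
    out$effective_time_min <- df$effective_time
  utils::write.csv(format(out, digits = 10, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the report files of a detection run
#'
#' Produces, in `dir`: `pulses.csv` (one row per detected pulse with its
#' 1-based sample index, occurrence time, amplitude, height and magnitude),
#' `ipi.csv` (one row per interval with the fitted trend, tunnel edges,
#' flag and suggestion) and `report.json` (configuration echo, stage-by-
#' stage removal log and outlier suggestions).  Output is deterministic
#' for a fixed input.
#'
#' @param detection a [detect_pulses()] result.
#' @param dir output directory (created if missing).
#' @param analysis optionally a matching [ipi_tunnel_analysis()]; computed
#'   from `detection` when omitted and at least two pulses exist.
#' @param seed seed to echo into the report.
#' @return Character vector of the files written, invisibly.
#' @export
write_report <- function(detection, dir, analysis = NULL, seed = NULL) {
  stopifnot(inherits(detection, "pulse_detection"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tt <- detection$series[[1L]]
  yy <- detection$series[[2L]]
  P <- detection$pulses
  pulses <- data.frame(
    pulse_number = seq_along(P), sample_index = P,
    time_min = tt[P], amplitude_ng_per_ml = yy[P],
    height = vapply(P, function(i) pulse_height(yy, i), numeric(1)),
    magnitude = vapply(P, function(i) pulse_magnitude(yy, P, i), numeric(1)))
  f_pulses <- file.path(dir, "pulses.csv")
  utils::write.csv(pulses, f_pulses, row.names = FALSE, quote = FALSE)

  if (is.null(analysis) && length(P) >= 2L)
    analysis <- ipi_tunnel_analysis(detection)
  if (!is.null(analysis) && nrow(analysis$ipis)) {
    d <- analysis$diagnosis
    ipi_tab <- data.frame(
      interval_number = d$interval, anchor_time_min = d$anchor_time,
      ipi_min = d$ipi,
      phi_min = analysis$tunnel$phi(d$anchor_time),
      lower_min = analysis$tunnel$lower(d$anchor_time),
      upper_min = analysis$tunnel$upper(d$anchor_time),
      flag = d$flag, suggestion = d$suggestion)
  } else {
    ipi_tab <- data.frame(interval_number = integer(0),
                          anchor_time_min = numeric(0), ipi_min = numeric(0),
                          phi_min = numeric(0), lower_min = numeric(0),
                          upper_min = numeric(0), flag = character(0),
                          suggestion = character(0))
  }
  f_ipi <- file.path(dir, "ipi.csv")
  utils::write.csv(ipi_tab, f_ipi, row.names = FALSE, quote = FALSE)

  report <- list(
    config = unclass(detection$config),
    seed = seed,
    n_samples = length(yy),
    n_pulses = length(P),
    stages = lapply(detection$stages, function(p) as.integer(p)),
    outliers = if (!is.null(analysis) && nrow(analysis$ipis))
      analysis$diagnosis[analysis$diagnosis$flag != "inside",
                         c("interval", "anchor_time", "ipi", "flag",
                           "suggestion", "detail")]
      else list())
  if (length(P) == 0L) report$note <- "zero pulses detected"
  f_json <- file.path(dir, "report.json")
  jsonlite::write_json(report, f_json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(c(f_pulses, f_ipi, f_json))
}

#' Read a scenario configuration file
#'
#' YAML (or JSON) description of a synthetic run: amplitude and
#' interspike-interval endpoints, spike half-life, clearance rate,
#' duration, grid step, and the sampling block (`ts`, `r`, `f`, `b`, `n`,
#' `seed`).  Missing fields fall back to package defaults.
#'
#' @param path path to a `.yaml`/`.yml`/`.json` file.
#' @return A list with `profile` (a [release_profile()]), `a`, `grid_step`
#'   and `sampling` (a [sampling_config()] or NULL when no sampling block
#'   is given).
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) stop("scenario file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  get_or <- function(name, default) if (is.null(cfg[[name]])) default
                                    else cfg[[name]]
  duration <- get_or("duration", 1000)
  profile <- release_profile(
    amplitude = unlist(get_or("amplitude", 1)),
    ipi = unlist(get_or("ipi", 60)),
    half_life = get_or("half_life", 2),
    duration = duration)
  a <- get_or("clearance_rate", log(2) / 60)
  grid_step <- get_or("grid_step", 0.05)
  sampling <- NULL
  if (!is.null(cfg$sampling)) {
    s <- cfg$sampling
    gs <- function(name, default) if (is.null(s[[name]])) default
                                  else s[[name]]
    ts <- gs("ts", 10); r <- gs("r", 1); f <- gs("f", 0)
    n <- gs("n", floor((duration - r - f) / ts) + 1)
    sampling <- sampling_config(Ts = ts, N = n, r = r, f = f,
                                b = gs("b", 0), seed = gs("seed", NULL),
                                noise_dist = gs("noise_dist", "uniform"))
  }
  list(profile = profile, a = a, grid_step = grid_step, sampling = sampling)
}

#' Export a plasma signal as CSV
#'
#' Two columns, `time_min` and `lh_ng_per_ml`, '.' decimal separator.
#'
#' @param signal a `plasma_signal`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_signal <- function(signal, path) {
  stopifnot(inherits(signal, "plasma_signal"))
  utils::write.csv(data.frame(time_min = signal$grid_times,
                              lh_ng_per_ml = signal$levels),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Plot a detection with its series and IPI tunnel
#'
#' Two stacked base-graphics panels: the series with detected occurrences,
#' and the IPI series inside its tunnel.
#'
#' @param x a `pulse_detection`.
#' @param analysis optional matching [ipi_tunnel_analysis()].
#' @param ... passed to the series panel's `plot`.
#' @return `x`, invisibly.
#' @export
plot.pulse_detection <- function(x, analysis = NULL, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(op))
  tt <- x$series[[1L]]; yy <- x$series[[2L]]
  graphics::plot(tt, yy, type = "o", pch = 20, cex = 0.6,
                 xlab = "time (min)", ylab = "LH (ng/ml)", ...)
  graphics::abline(v = x$times, col = "steelblue", lty = 3)
  graphics::points(x$times, x$amplitudes, col = "red", pch = 17)
  if (is.null(analysis) && length(x$pulses) >= 3L)
    analysis <- ipi_tunnel_analysis(x)
  if (!is.null(analysis) && nrow(analysis$ipis)) {
    at <- analysis$ipis$anchor_time
    grid_t <- seq(min(at), max(at), length.out = 200L)
    ylim <- range(analysis$ipis$ipi, analysis$tunnel$upper(grid_t), 0)
    graphics::plot(at, analysis$ipis$ipi, pch = 19, col = "blue",
                   ylim = ylim, xlab = "time (min)", ylab = "IPI (min)")
    graphics::lines(grid_t, analysis$tunnel$phi(grid_t), lty = 2)
    graphics::lines(grid_t, analysis$tunnel$lower(grid_t))
    graphics::lines(grid_t, analysis$tunnel$upper(grid_t))
  }
  invisible(x)
}
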