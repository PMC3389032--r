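test_that("height is the elevation above the series minimum", {
  y <- c(0.4, 2.1, 0.1, 1.5)
  expect_equal(pulse_height(y, 2), 2.0)
  expect_equal(pulse_height(y, 3), 0)
  # invariant under adding a constant
  expect_equal(pulse_height(y + 3.7, 2), pulse_height(y, 2))
})

test_that("magnitude is the geometric mean of the two-sided elevations", {
  # flanking pulses at the ends; left minimum 0.6, right minimum 0.2
  y <- c(3, 0.6, 2.0, 0.2, 3)
  m <- pulse_magnitude(y, P = c(1L, 5L), i = 3L)
  expect_equal(m, sqrt(1.4 * 1.8))
  expect_equal(round(m, 3), 1.587)
  # U = V reduces to U
  y2 <- c(3, 0.5, 2.0, 0.5, 3)
  expect_equal(pulse_magnitude(y2, c(1L, 5L), 3L), 1.5)
  # peak not rising above a side minimum has magnitude zero
  y3 <- c(3, 2.0, 2.0, 0.2, 3)
  expect_equal(pulse_magnitude(y3, c(1L, 5L), 3L), 0)
  # geometric mean is less sensitive than the arithmetic mean to a shift
  # of the shallower (larger-elevation) side's baseline
  y4 <- c(3, 0.6, 2.0, 0.7, 3)          # right baseline raised by 0.5
  g0 <- sqrt(1.4 * 1.8); g1 <- pulse_magnitude(y4, c(1L, 5L), 3L)
  a0 <- (1.4 + 1.8) / 2; a1 <- (1.4 + 1.3) / 2
  expect_lt(abs(g1 - g0), abs(a1 - a0))
})

test_that("relative magnitude is symmetric and handles flat peaks", {
  y <- c(2, 1, 2)
  expect_equal(relative_magnitude(y, 1, 3), 1)
  expect_equal(relative_magnitude(y, 3, 1), relative_magnitude(y, 1, 3))
  # coincides with magnitude when the same minima flank the peak
  y2 <- c(1.8, 0.6, 2.0, 0.2, 2.2)
  expect_equal(relative_magnitude(y2, 1, 3) > 0, TRUE)
  expect_equal(pulse_magnitude(y2, c(1L, 5L), 3L),
               sqrt((2.0 - 0.6) * (2.0 - 0.2)))
  expect_equal(relative_magnitude(y2, 2, 4), 0)   # valley, not a peak
})

test_that("forward search seeds one candidate per clean pulse", {
  # exactly periodic constructed series: pulse summit every 6 samples
  ser <- toy_pulse_series(rep(2, 8))
  y <- ser$value
  P <- initialize_pulses(y, Ts = 10, Tp = 40)
  expect_equal(length(P), 8L)
  expect_true(all(diff(P) == 6L))
  expect_true(all(y[P] == max(y)))
  # ties resolved to the earliest index: the very first summit is kept
  expect_equal(P[1], 4L)
  expect_error(initialize_pulses(y[1:8], 10, 40), "shorter")
})

test_that("global relative criterion uses the median height", {
  y <- c(0, 1, 0, 1, 0, 0.1, 0)
  P <- c(2L, 4L, 6L)
  expect_equal(apply_global_relative(y, P, 0.2), c(2L, 4L))
  # equal heights survive any threshold below one
  expect_equal(apply_global_relative(y, c(2L, 4L), 0.99), c(2L, 4L))
  # a single huge peak does not drag normals out (median, not mean)
  y2 <- c(0, 0.5, 0, 0.5, 0, 0.5, 0, 10, 0)
  P2 <- c(2L, 4L, 6L, 8L)
  expect_equal(apply_global_relative(y2, P2, 0.2), P2)
  # mean-based reference would have removed them
  expect_lt(0.5 / mean(c(0.5, 0.5, 0.5, 10)), 0.2)
})

test_that("semi-local criterion removes small interior peaks at fixpoint", {
  # bump of magnitude m between two pulses with relative magnitude 2
  mk <- function(m) c(0, 2, 0, m, 0, 2, 0)
  P <- c(2L, 4L, 6L)
  expect_equal(apply_semilocal(mk(0.1), P, 0.2), c(2L, 6L))
  # kept exactly at the threshold (strict inequality removes)
  expect_equal(apply_semilocal(mk(0.4), P, 0.2), P)
  expect_equal(apply_semilocal(mk(0.39), P, 0.2), c(2L, 6L))
  # cascading removals reach a fixpoint
  y <- c(0, 2, 0.5, 0.6, 0.5, 0.7, 0.5, 2, 0)
  P2 <- c(2L, 4L, 6L, 8L)
  out <- apply_semilocal(y, P2, 0.2)
  expect_equal(out, c(2L, 8L))
})

test_that("global absolute criterion removes sub-threshold magnitudes", {
  y <- c(0, 2, 0, 0.05, 0, 2, 0)
  P <- c(2L, 4L, 6L)
  expect_equal(apply_global_absolute(y, P, 0), P)
  expect_equal(apply_global_absolute(y, P, 0.1), c(2L, 6L))
  # kept at the exact threshold
  expect_equal(apply_global_absolute(y, P, 0.05), P)
})

test_that("retrieval recovers a cleanly skipped pulse", {
  # IPI 60 with Tp = 80: the forward search skips pulses; retrieval must
  # bring the detected set back to one pulse per true pulse
  fix <- make_fixture("constant60", seed = 1)
  det <- detect_pulses(fix$series, detection_config(Ts = 10, Tp = 80))
  expect_equal(length(det$pulses), nrow(fix$truth))
  expect_true(all(diff(det$times) == 60))
  # a gap containing only sub-threshold bumps is left unchanged
  y <- c(0, 2, 0, 0.1, 0.05, 0.1, 0, 2, 0)
  expect_equal(retrieve_missed(y, c(2L, 8L), 0.2), c(2L, 8L))
})

test_that("lowering the relative threshold recovers a small pulse", {
  # ten regular pulses and one small one in a doubled gap; its magnitude
  # sits between 0.1 and 0.2 of the flanking relative magnitude
  ser <- toy_pulse_series(c(2, 2, 2, 2, 0.28, 2, 2, 2, 2, 2))
  cfg2 <- detection_config(Ts = 10, Tp = 40, lambda_r = 0.2)
  cfg1 <- detection_config(Ts = 10, Tp = 40, lambda_r = 0.1)
  det2 <- detect_pulses(ser, cfg2)
  det1 <- detect_pulses(ser, cfg1)
  small_summit <- 6L * 5L - 2L             # summit of the 5th (small) pulse
  expect_false(small_summit %in% det2$pulses)
  expect_true(small_summit %in% det1$pulses)
  expect_equal(setdiff(det1$pulses, det2$pulses), small_summit)
})

test_that("sharpness coefficient separates artefacts from noised summits", {
  y <- c(1.0, 0.2, 2.0, 0.3, 1.1)
  expect_equal(round(sharpness_coefficient(y, 3), 3), 0.457)
  # monotone decay after the peak rebounds nowhere: coefficient 0
  y2 <- c(0.1, 1, 2, 1.4, 1.0)
  expect_equal(sharpness_coefficient(y2, 3), 0)
  # edges without rank-2 neighbours are never removable
  expect_equal(sharpness_coefficient(y, 2), 0)
  # a noised genuine summit rebounds on the noise scale, far below its
  # magnitude: coefficient stays small
  y3 <- c(0.1, 0.5, 1.2, 1.9, 1.85, 2.0, 1.6, 1.3, 1.0, 0.8)
  expect_lt(sharpness_coefficient(y3, 6, P = 6L), 0.1)
})

test_that("3-point peak removal respects pattern, threshold and rank", {
  y <- c(1.0, 0.2, 2.0, 0.3, 1.1)
  expect_equal(remove_3point_peaks(y, 3L, 0.1), integer(0))
  expect_equal(remove_3point_peaks(y, 3L, 1), 3L)     # threshold disables
  # neighbour that is not a local minimum: pattern precondition fails
  y2 <- c(0.1, 0.5, 2.0, 0.3, 1.1)
  expect_equal(remove_3point_peaks(y2, 3L, 0.1), 3L)
  # at rank 2 the same artefact repeated at double resolution is caught
  y3 <- c(1.0, 0.9, 0.2, 0.25, 2.0, 0.35, 0.3, 1.05, 1.1)
  expect_equal(remove_3point_peaks(y3, 5L, 0.1, rank = 2L), integer(0))
})

test_that("detection on noise-free synthetic series matches ground truth", {
  fix <- make_fixture("s4_ramp", seed = 1, b = 0)
  det <- detect_pulses(fix$series)
  expect_equal(length(det$pulses), nrow(fix$truth))
  expect_true(all(abs(det$times - fix$truth$pulse_time) <= 10))
  # deterministic: identical on a second run
  det2 <- detect_pulses(fix$series)
  expect_identical(det$pulses, det2$pulses)
})

test_that("relative criteria are scale-free; the absolute one is not", {
  fix <- make_fixture("s4_ramp", seed = 3, b = 0.08)
  ser <- as.data.frame(fix$series)
  cfg <- detection_config(Ts = 10)
  base <- detect_pulses(ser, cfg)$pulses
  for (c_scale in c(0.01, 7)) {
    scaled <- ser
    scaled$value <- scaled$value * c_scale
    expect_identical(detect_pulses(scaled, cfg)$pulses, base)
  }
  # lambda_a acts on the absolute scale: shrinking the series removes all
  cfg_a <- detection_config(Ts = 10, lambda_a = 1)
  shrunk <- ser
  shrunk$value <- shrunk$value * 0.01
  expect_lt(length(suppressWarnings(detect_pulses(shrunk, cfg_a))$pulses),
            length(base))
})

test_that("incremental computations agree with a brute-force oracle", {
  for (seed in 1:20) {
    y <- random_small_series(sample(12:30, 1), seed)
    N <- length(y)
    peaks <- which(vapply(seq_len(N), function(i)
      dynpeak:::is_local_max(y, i), logical(1)))
    P <- peaks
    for (i in seq_len(N)) {
      expect_equal(pulse_height(y, i), brute_height(y, i))
    }
    # compare magnitudes while removing pulses one at a time, so the
    # flanks of the survivors keep changing
    while (length(P) > 1) {
      for (i in P)
        expect_equal(pulse_magnitude(y, P, i), brute_magnitude(y, P, i))
      for (k in seq_len(length(P) - 1))
        expect_equal(relative_magnitude(y, P[k], P[k + 1]),
                     brute_relative_magnitude(y, P[k], P[k + 1]))
      P <- P[-sample(length(P), 1)]
    }
  }
})

test_that("the pulse vector stays strictly increasing on local maxima", {
  for (seed in c(2, 9, 23)) {
    fix <- make_fixture("s4_ramp", seed = seed, b = 0.16)
    det <- detect_pulses(fix$series)
    y <- fix$series$value
    for (P in det$stages) {
      expect_true(all(diff(P) > 0))
    }
    expect_true(all(vapply(det$pulses, function(i)
      dynpeak:::is_local_max(y, i), logical(1))))
  }
})

test_that("configuration bounds are enforced", {
  expect_error(detection_config(Ts = 10, Tp = 15), "twice")
  expect_error(detection_config(Ts = 10, lambda_r = 1.2), "lambda_r")
  expect_error(detection_config(Ts = 10, lambda_a = -1), "lambda_a")
  expect_error(detection_config(Ts = 10, lambda_3p = 0), "lambda_3p")
})
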