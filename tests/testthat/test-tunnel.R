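test_that("IPI series anchors each interval at the later pulse", {
  ip <- ipi_series(c(10, 70, 130))
  expect_equal(ip$ipi, c(60, 60))
  expect_equal(ip$anchor_time, c(70, 130))
  # removing an interior pulse merges two intervals into their sum
  ip2 <- ipi_series(c(10, 70, 190, 250))
  expect_equal(ip2$ipi, c(60, 120, 60))
  expect_warning(ipi_series(42), "fewer than two")
  expect_error(ipi_series(c(10, 10, 30)), "strictly increasing")
  # telescoping: the intervals sum to the total span
  tt <- cumsum(c(5, runif(9, 40, 90)))
  expect_equal(sum(ipi_series(tt)$ipi), max(tt) - min(tt))
})

test_that("pulses on a nominal grid give period-multiple IPIs", {
  fix <- make_fixture("constant60", seed = 1)
  det <- detect_pulses(fix$series)
  ip <- ipi_series(det$times)
  expect_true(all(ip$ipi %% 10 == 0))
  expect_true(all(ip$ipi == 60))
})

test_that("cubic trend fitting matches a normal-equations oracle", {
  # exact interpolation of data on a cubic
  tt <- c(100, 250, 400, 550, 700, 850)
  coefs <- c(60, 0.02, -1e-4, 5e-8)
  vv <- coefs[1] + coefs[2] * tt + coefs[3] * tt^2 + coefs[4] * tt^3
  tr <- fit_cubic_trend(data.frame(anchor_time = tt, ipi = vv))
  expect_equal(tr$coefficients, coefs, tolerance = 1e-6)
  expect_equal(tr$fn(tt), vv, tolerance = 1e-8)
  # constant IPIs give a constant trend
  trc <- fit_cubic_trend(data.frame(anchor_time = tt, ipi = rep(60, 6)))
  expect_equal(trc$fn(c(0, 123, 999)), rep(60, 3), tolerance = 1e-8)
  # ten random instances against an independent normal-equations solve;
  # the fitted values are the well-conditioned comparison
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(5:15, 1)
    t_r <- sort(runif(n, 0, 1000))
    v_r <- runif(n, 40, 120)
    tr_r <- fit_cubic_trend(data.frame(anchor_time = t_r, ipi = v_r))
    b <- brute_polyfit(t_r, v_r, 3)
    fitted_oracle <- b[1] + b[2] * t_r + b[3] * t_r^2 + b[4] * t_r^3
    expect_equal(tr_r$fn(t_r), fitted_oracle, tolerance = 1e-8)
  }
  # degree falls back for short series
  tr2 <- fit_cubic_trend(data.frame(anchor_time = c(60, 120), ipi = c(55, 65)))
  expect_equal(tr2$degree, 1L)
  expect_equal(tr2$fn(90), 60)
  tr1 <- fit_cubic_trend(data.frame(anchor_time = 60, ipi = 55))
  expect_equal(tr1$fn(200), 55)
})

test_that("tunnel edges scale the trend and keep a constant ratio", {
  phi <- function(t) rep(100, length(t))
  tun <- build_tunnel(phi, pulse_times = c(0, 100, 200), alpha = 0.6,
                      beta = 0.6)
  expect_equal(tun$lower(150), 40)
  expect_equal(tun$upper(150), 160)
  # ratio (1 + beta) / (1 - alpha) = 4 everywhere the trend is positive
  tr <- fit_cubic_trend(data.frame(anchor_time = seq(60, 900, by = 60),
                                   ipi = 60 + seq(0, 28, by = 2)))
  tun2 <- build_tunnel(tr, pulse_times = seq(0, 900, by = 60))
  grid <- seq(0, 900, by = 7)
  expect_true(all(tun2$lower(grid) > 0))
  expect_equal(tun2$upper(grid) / tun2$lower(grid), rep(4, length(grid)))
  # degenerate width: alpha = beta = 0 is rejected (tunnel must be a band)
  expect_error(build_tunnel(phi, c(0, 100), alpha = 0, beta = 0.6), "alpha")
  # negative trend values are floored at zero with a warning
  expect_warning(tun3 <- build_tunnel(function(t) t - 50, c(0, 100),
                                      alpha = 0.5, beta = 0.5), "floor")
  expect_equal(tun3$lower(0), 0)
})

test_that("outlier classification is strict against the tunnel edges", {
  tt <- seq(60, 600, by = 60)
  ip <- ipi_series(c(0, tt))
  tr <- fit_cubic_trend(ip)
  tun <- build_tunnel(tr, c(0, tt))
  # all intervals on the trend lie inside for any positive widths
  expect_true(all(classify_outliers(ip, tun) == "inside"))
  # a merged double interval in a regular series of realistic length is
  # flagged above (short series would let the cubic chase the outlier)
  reg <- seq(0, 960, by = 60)
  merged_times <- setdiff(reg, 480)
  merged <- ipi_series(merged_times)
  tun_m <- build_tunnel(fit_cubic_trend(merged), merged_times)
  fl <- classify_outliers(merged, tun_m)
  expect_equal(as.character(fl[merged$ipi == 120]), "above")
  expect_true(all(fl[merged$ipi == 60] == "inside"))
  # an extra pulse near (but off) the midpoint leaves one sub-interval
  # under half the expected duration: flagged below
  split_times <- sort(c(reg, 480 + 20))
  split <- ipi_series(split_times)
  tun_s <- build_tunnel(fit_cubic_trend(split), split_times)
  fl_s <- classify_outliers(split, tun_s)
  expect_equal(as.character(fl_s[split$ipi == 20]), "below")
})

test_that("diagnosis annotates merged, split and break patterns", {
  # lack of detection: constant-60 pulses with one deleted
  fix <- make_fixture("constant60", seed = 1)
  det <- detect_pulses(fix$series)
  drop <- 8L
  lesioned <- det
  lesioned$times <- det$times[-drop]
  lesioned$pulses <- det$pulses[-drop]
  ip <- ipi_series(lesioned$times)
  tun <- build_tunnel(fit_cubic_trend(ip), lesioned$times)
  diag <- diagnose_outliers(ip, tun, lesioned$times, series = det$series)
  out <- diag[diag$flag == "above", ]
  expect_equal(nrow(out), 1L)
  expect_equal(out$ipi, 120)
  # merged interval is exactly twice the mean of its neighbours
  k <- out$interval
  expect_equal(out$ipi / mean(c(ip$ipi[k - 1], ip$ipi[k + 1])), 2.0)
  expect_match(out$suggestion, "lack of detection")

  # over-detection: an extra pulse near the midpoint of a gap leaves one
  # sub-interval below the tunnel
  times2 <- sort(c(det$times, det$times[8] + 20))
  ip2 <- ipi_series(times2)
  expect_equal(sort(ip2$ipi[ip2$anchor_time %in%
                              (det$times[8] + c(20, 60))]),
               c(20, 40))
  tun2 <- build_tunnel(fit_cubic_trend(ip2), times2)
  diag2 <- diagnose_outliers(ip2, tun2, times2, series = det$series)
  below <- diag2[diag2$flag == "below", ]
  expect_gte(nrow(below), 1L)
  expect_match(below$suggestion[1], "over-detection")
  expect_match(below$detail[1], "weaker flanking pulse")
})

test_that("a sudden frequency break is located within one interval", {
  # steep frequency collapse (one pulse per 40 min to one per 160 min);
  # a milder step would sit inside the default 40-160% tunnel
  prof <- release_profile(1, rbind(c(0, 40), c(500, 40), c(510, 160),
                                   c(1000, 160)), duration = 1000)
  sig <- simulate_plasma(prof)
  ser <- sample_series(sig, sampling_config(Ts = 10, N = 100, r = 1,
                                            seed = 1))
  det <- detect_pulses(ser)
  an <- ipi_tunnel_analysis(det, trend = "moving")
  breaks <- an$diagnosis[an$diagnosis$flag == "above" &
                           grepl("break", an$diagnosis$suggestion), ]
  expect_gte(nrow(breaks), 1L)
  expect_lte(abs(breaks$break_time[1] - 500), 110)
  # intervals before the break stay inside the moving tunnel
  pre <- an$diagnosis$anchor_time < 500
  expect_true(all(an$diagnosis$flag[pre] == "inside"))
})

test_that("the suggested threshold correction clears the outlier", {
  # a small pulse in a doubled gap: the default threshold misses it and
  # the tunnel flags the merged interval; the corrected threshold
  # recovers the pulse, removes the outlier and keeps every genuine pulse
  heights <- rep(2, 16); heights[8] <- 0.28
  ser <- toy_pulse_series(heights)
  an2 <- ipi_tunnel_analysis(detect_pulses(ser, detection_config(
    Ts = 10, Tp = 40, lambda_r = 0.2)))
  an1 <- ipi_tunnel_analysis(detect_pulses(ser, detection_config(
    Ts = 10, Tp = 40, lambda_r = 0.1)))
  expect_gte(sum(an2$flags == "above"), 1L)
  expect_lt(sum(an1$flags == "above"), sum(an2$flags == "above"))
  expect_true(all(an1$ipis$ipi == 60))
})
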