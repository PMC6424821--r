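test_that("correlograms localize a fixed lag and conserve pair counts", {
  ref <- seq(1, 99, by = 0.5)
  target <- ref + 0.0042
  ccg <- cross_correlogram(ref, target, window_s = 0.05, bin_s = 0.001)
  expect_equal(ccg$prob[which.min(abs(ccg$lag_ms - 4.5))], 1)
  expect_equal(ccg$lag_ms[which.max(ccg$prob)], 4.5, tolerance = 1e-9)
  expect_equal(sum(ccg$prob), 1)
  # mass conservation against direct pair counting
  trains <- withr::with_seed(3, list(r = sort(stats::runif(400, 0, 100)),
                                     t = sort(stats::runif(600, 0, 100))))
  ccg2 <- cross_correlogram(trains$r, trains$t, window_s = 0.2, bin_s = 0.005)
  lags <- outer(trains$t, trains$r, "-")
  n_pairs <- sum(lags >= -0.2 & lags < 0.2)
  expect_equal(sum(ccg2$prob) * ccg2$n_ref, n_pairs)
  expect_error(cross_correlogram(numeric(), 1), "non-empty")
})

test_that("independent Poisson pairs give flat correlograms at rate*bin", {
  lambda <- 8; dur <- 500
  tr <- withr::with_seed(11, list(
    r = sort(stats::runif(2 * dur, 0, dur)),
    t = sort(stats::runif(lambda * dur, 0, dur))))
  ccg <- cross_correlogram(tr$r, tr$t, window_s = 0.1, bin_s = 0.002)
  expected <- lambda * 0.002
  expect_lt(abs(mean(ccg$prob) - expected) / expected, 0.05)
  expect_lt(stats::sd(ccg$prob) / expected, 0.3)
})

test_that("theta-comodulated pairs show cycle-periodic correlograms", {
  cfg <- session_config(duration = 400, n_pyr = 1, n_fsi = 1, pyr_rate = 4,
                        fsi_rate = 10, place_depth = 0, cycle_jitter = 0,
                        theta_kappa = c(pyr = 1.5, msn = 0, fsi = 1.5,
                                        tan = 0), seed = 19)
  s <- generate_session(cfg)
  ccg <- cross_correlogram(s$spikes$pyr1, s$spikes$fsi1, window_s = 0.2,
                           bin_s = 0.001)
  sm <- stats::filter(ccg$prob, rep(1 / 11, 11), sides = 2)
  # autocovariance of the smoothed correlogram peaks near one cycle (125 ms)
  ac <- stats::acf(na.omit(as.numeric(sm)), lag.max = 180, plot = FALSE)$acf
  period_band <- ac[115:140]
  trough_band <- ac[50:80]
  expect_gt(max(period_band), max(trough_band))
})

test_that("surrogate bands flag injected coupling but not comodulation", {
  expect_true(pair_exceeds_band(seed = 301, coupled = TRUE))
  expect_true(pair_exceeds_band(seed = 302, coupled = TRUE))
  expect_false(pair_exceeds_band(seed = 303, coupled = FALSE))
  expect_false(pair_exceeds_band(seed = 304, coupled = FALSE))
})

test_that("rate scores follow the closed form and are antisymmetric", {
  on_ep <- data.frame(start = 10, end = 20)
  off_ep <- data.frame(start = 0, end = 10)
  spk_off <- seq(0.05, 9.95, by = 0.1)
  expect_equal(light_rate_score(spk_off, on_ep, off_ep), -1)
  both <- c(spk_off, spk_off + 10)
  expect_equal(light_rate_score(both, on_ep, off_ep), 0)
  set.seed(2)
  spk <- sort(c(stats::runif(500, 0, 10), stats::runif(250, 10, 20)))
  s1 <- light_rate_score(spk, on_ep, off_ep)
  s2 <- light_rate_score(spk, off_ep, on_ep)
  expect_equal(s1, -s2)
  expect_true(is.na(suppressMessages(
    light_rate_score(numeric(), on_ep, off_ep))))
})

test_that("generator suppression factors map onto predicted rate scores", {
  for (s_fac in c(0, 0.25)) {
    cfg <- session_config(
      duration = 400, n_fsi = 1, n_pyr = 0, fsi_rate = 10, seed = 7,
      light_epochs = list(list(start = 100, end = 200,
                               factors = c(fsi1 = s_fac)),
                          list(start = 300, end = 400,
                               factors = c(fsi1 = s_fac))))
    sess <- generate_session(cfg)
    sc <- light_rate_score(sess$spikes$fsi1,
                           data.frame(start = c(100, 300), end = c(200, 400)),
                           data.frame(start = c(0, 200), end = c(100, 300)))
    expected <- (s_fac - 1) / (s_fac + 1)
    se <- sqrt(1 / (10 * 200) * 2)  # Poisson error propagated to the score
    expect_lt(abs(sc - expected), 3 * max(se, 0.02))
  }
})

test_that("score densities normalize and resolve bimodal structure", {
  d0 <- score_density(rep(0, 20))
  expect_equal(d0$score[which.max(d0$density)], 0, tolerance = 0.01)
  dx <- diff(d0$score[1:2])
  expect_lt(abs(sum(d0$density) * dx - 1), 1e-3)
  set.seed(6)
  bim <- c(stats::rnorm(100, -0.9, 0.03), stats::rnorm(100, 0, 0.03))
  db <- score_density(bim)
  peaks <- db$score[which(diff(sign(diff(db$density))) == -2) + 1]
  expect_true(any(abs(peaks + 0.9) < 0.1) && any(abs(peaks) < 0.1))
  expect_error(score_density(0.5), "two finite")
})

test_that("Rayleigh depth obeys limits and rotation invariance", {
  expect_equal(theta_modulation_depth(phases = rep(1.3, 50)), 1)
  unif <- vm_phases(50000, 0, seed = 4)
  expect_lt(theta_modulation_depth(phases = unif), 0.02)
  vm <- vm_phases(20000, 2, seed = 5)
  r1 <- theta_modulation_depth(phases = vm)
  r2 <- theta_modulation_depth(phases = (vm + 1.1) %% (2 * pi))
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("PSP kinetics recover ramp rise times, scaling, and pulse ratios", {
  t <- seq(0, 0.1, by = 1e-5)
  v <- numeric(length(t))
  ramp <- t >= 0.02 & t <= 0.03
  v[ramp] <- (t[ramp] - 0.02) / 0.01          # 0 -> 1 mV over 10 ms
  v[t > 0.03] <- pmax(0, 1 - (t[t > 0.03] - 0.03) / 0.02)
  k <- psp_kinetics(t, v, baseline = c(0, 0.02))
  expect_equal(nrow(k$events), 1)
  expect_equal(k$events$rise_time, 0.006, tolerance = 1e-4)
  expect_equal(k$events$amplitude, 1, tolerance = 1e-6)
  # scale law
  k3 <- psp_kinetics(t, 3 * v, baseline = c(0, 0.02))
  expect_equal(k3$events$amplitude, 3, tolerance = 1e-6)
  expect_equal(k3$events$rise_time, k$events$rise_time, tolerance = 1e-6)
  # paired pulses with equal amplitude: PPR = 1
  v2 <- v + c(rep(0, 5000), v[1:(length(v) - 5000)])
  k2 <- psp_kinetics(t, v2, baseline = c(0, 0.02),
                     stim_times = c(0.02, 0.07))
  expect_equal(k2$ppr, 1, tolerance = 0.05)
  # trace that never leaves baseline: no event
  flat <- rep(0, length(t))
  expect_equal(nrow(psp_kinetics(t, flat, baseline = c(0, 0.02))$events), 0)
})
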