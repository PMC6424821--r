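test_that("session generation is deterministic and substream-stable", {
  cfg <- recovery_config(seed = 11, n_pyr = 10, n_assemblies = 1,
                         members_per = 4, duration = 60)
  s1 <- generate_session(cfg)
  s2 <- generate_session(cfg)
  expect_identical(s1$spikes, s2$spikes)
  expect_identical(s1$position, s2$position)
  expect_identical(s1$cycles$boundaries, s2$cycles$boundaries)

  # adding neurons must not perturb existing trains (per-neuron substreams)
  cfg_big <- recovery_config(seed = 11, n_pyr = 12, n_assemblies = 1,
                             members_per = 4, duration = 60)
  s3 <- generate_session(cfg_big)
  for (id in paste0("pyr", 1:10))
    expect_identical(s1$spikes[[id]], s3$spikes[[id]])
})

test_that("config validation rejects inconsistent specifications", {
  expect_error(session_config(duration = -1), "duration")
  expect_error(session_config(
    duration = 10,
    assemblies = list(list(members = "pyr999", rate = 1, participation = 0.5))
  ), "unknown neuron")
  expect_error(session_config(
    duration = 10,
    assemblies = list(list(members = "pyr1", rate = 1, participation = 1.5))
  ), "participation")
  expect_error(session_config(
    duration = 10, n_fsi = 1,
    couplings = data.frame(pre = "pyr1", post = "fsi1", latency_ms = 0,
                           efficacy = 0.5)
  ), "latencies")
  expect_error(session_config(
    duration = 10,
    light_epochs = list(list(start = 5, end = 20, factors = c(pyr1 = 0)))
  ), "light epochs")
})

test_that("zero assemblies and zero couplings give plain modulated trains", {
  cfg <- session_config(duration = 60, n_pyr = 5, seed = 2)
  s <- generate_session(cfg)
  expect_length(s$truth$assembly_memberships, 0)
  expect_null(s$truth$coupling_graph)
  expect_length(s$spikes, 5)
})

test_that("empirical rates stay within Poisson error of configured rates", {
  cfg <- recovery_config(seed = 5, duration = 1200)
  s <- generate_session(cfg)
  dur <- cfg$duration
  member_of <- table(unlist(s$truth$assembly_memberships))
  for (id in cfg$ids) {
    extra <- if (!is.null(member_of[id]) && !is.na(member_of[id]))
      member_of[[id]] * 1 * 0.8 else 0
    expected <- cfg$rates[[id]] + extra
    se <- sqrt(expected * dur) / dur
    expect_lt(abs(length(s$spikes[[id]]) / dur - expected), 4 * se)
  }
})

test_that("suppression factor 0 silences a neuron within the light epoch", {
  cfg <- session_config(
    duration = 120, n_pyr = 2, n_fsi = 1, fsi_rate = 10, seed = 9,
    couplings = data.frame(pre = "pyr1", post = "fsi1", latency_ms = 4,
                           efficacy = 0.5),
    light_epochs = list(list(start = 40, end = 80, factors = c(fsi1 = 0)))
  )
  s <- generate_session(cfg)
  inside <- s$spikes$fsi1 >= 40 & s$spikes$fsi1 < 80
  expect_equal(sum(inside), 0)
  expect_gt(sum(!inside), 0)
})

test_that("monosynaptic transmission probability matches configured efficacy", {
  cfg <- session_config(
    duration = 600, n_pyr = 1, n_fsi = 1, pyr_rate = 4, fsi_rate = 0.5,
    place_depth = 0, seed = 13,
    couplings = data.frame(pre = "pyr1", post = "fsi1", latency_ms = 4,
                           efficacy = 0.2)
  )
  s <- generate_session(cfg)
  pre <- s$spikes$pyr1
  post <- s$spikes$fsi1
  hits <- vapply(pre, function(p)
    any(post >= p + 0.0025 & post <= p + 0.0055), TRUE)
  p_hat <- mean(hits)
  se <- sqrt(0.2 * 0.8 / length(pre))
  expect_lt(abs(p_hat - 0.2), 3 * se + 0.5 * 0.003)  # + baseline coincidences
})

test_that("theta-modulated neurons show the configured phase locking order", {
  depths <- vapply(c(0, 0.5, 2), function(kap) {
    cfg <- session_config(duration = 300, n_pyr = 1, pyr_rate = 5,
                          place_depth = 0,
                          theta_kappa = c(pyr = kap, msn = 0, fsi = 0, tan = 0),
                          seed = 21)
    s <- generate_session(cfg)
    theta_modulation_depth(s$spikes$pyr1, s$cycles)
  }, 0)
  expect_true(all(diff(depths) > 0))
})

test_that("co-members correlate more strongly than non-members in 25-ms bins", {
  cfg <- recovery_config(seed = 31, n_pyr = 12, n_assemblies = 1,
                         members_per = 4, duration = 600,
                         participation = 0.4)
  s <- generate_session(cfg)
  bz <- bin_and_zscore(s$spikes, c(0, 600))
  C <- tcrossprod(bz$Z) / ncol(bz$Z)
  mem <- match(s$truth$assembly_memberships[[1]], bz$included)
  non <- setdiff(seq_along(bz$included), mem)
  co <- C[mem, mem][upper.tri(diag(length(mem)))]
  bg <- C[non, non][upper.tri(diag(length(non)))]
  expect_gt(mean(co), mean(bg))
})

test_that("waveform bank geometry follows the separation parameter", {
  wf <- generate_waveforms(c(fsi = 100, msn = 100, tan = 100),
                           separation = 5, seed = 2)
  sil <- cluster::silhouette(as.integer(factor(wf$labels)),
                             dist(scale(wf$features)))
  expect_gt(mean(sil[, "sil_width"]), 0.5)
  # FSI templates narrowest
  durs <- rowSums(wf$features[, 1:2])
  expect_lt(mean(durs[wf$labels == "fsi"]), mean(durs[wf$labels == "msn"]))
  expect_lt(mean(durs[wf$labels == "msn"]), mean(durs[wf$labels == "tan"]))

  # degenerate cases
  wf0 <- generate_waveforms(c(fsi = 20, msn = 20, tan = 20),
                            separation = 0, seed = 3)
  expect_lt(abs(mclust::adjustedRandIndex(
    stats::kmeans(scale(wf0$features), 3, nstart = 10)$cluster,
    wf0$labels)), 0.15)
  wf1 <- generate_waveforms(c(0, 25, 0), separation = 5, seed = 4)
  expect_true(all(wf1$labels == "msn"))
  expect_equal(nrow(wf1$waveforms), 25)
})

test_that("trajectory dwell fraction tracks the preference parameter", {
  pos <- generate_cpp_trajectory(900, preference = 0.75, seed = 3)
  lab <- label_positions(pos)
  frac <- sum(lab == "A") / sum(lab %in% c("A", "B"))
  se <- sqrt(0.75 * 0.25 / sum(lab %in% c("A", "B")))
  expect_lt(abs(frac - 0.75), 3 * se)

  pos1 <- generate_cpp_trajectory(300, preference = 1, seed = 4)
  expect_true(all(label_positions(pos1) == "A"))
  expect_equal(preference_score(pos1, target = "A")$score, 1)

  pos5 <- generate_cpp_trajectory(1800, preference = 0.5, seed = 5)
  expect_lt(abs(preference_score(pos5, target = "A")$score), 0.05)
})
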