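test_that("binning and z-scoring follow the two-level example", {
  bz <- bin_and_zscore(list(A = c(0.010, 0.030), B = numeric()),
                       c(0, 0.1), 0.025)
  expect_equal(ncol(bz$Z), 4)
  expect_equal(bz$excluded, "B")
  expect_equal(unname(bz$Z["A", ]), c(1, 1, -1, -1))
})

test_that("retained rows are standardized; constant rows are excluded", {
  trains <- poisson_trains(8, 3, 200, seed = 4)
  trains$constant <- seq(0.0125, 200, by = 0.025)  # one spike every bin
  bz <- bin_and_zscore(trains, c(0, 200), 0.025)
  expect_true("constant" %in% bz$excluded)
  expect_true(all(abs(rowMeans(bz$Z)) < 1e-9))
  expect_true(all(abs(apply(bz$Z, 1, function(x)
    sqrt(mean((x - mean(x))^2))) - 1) < 1e-9))
  expect_error(bin_and_zscore(list(A = numeric(), B = numeric()), c(0, 1)),
               "zero count variance")
})

test_that("pattern counting needs more bins than neurons", {
  trains <- list(n1 = 0.01, n2 = 0.03, n3 = 0.055, n4 = 0.08,
                 n5 = c(0.01, 0.03))
  bz <- bin_and_zscore(trains, c(0, 0.1), 0.025)  # 4 bins, 5 neurons
  expect_error(count_significant_patterns(bz), "more bins than neurons")
})

test_that("duplicated spike trains produce a significant pattern", {
  trains <- poisson_trains(20, 2, 500, seed = 8)
  trains$dup <- trains$n1
  bz <- bin_and_zscore(trains, c(0, 500))
  expect_gte(count_significant_patterns(bz), 1)
  # eigen oracle: the duplicate pair alone carries eigenvalue ~2
  C <- tcrossprod(bz$Z) / ncol(bz$Z)
  i <- match(c("n1", "dup"), bz$included)
  expect_gt(max(eigen(C[i, i])$values), 1.9)
})

test_that("a single embedded assembly is recovered exactly at high SNR", {
  # the 2-SD member rule needs members to be a minority of the population
  cfg <- recovery_config(seed = 17, n_pyr = 40, n_assemblies = 1,
                         members_per = 5, duration = 900,
                         rate = 2, participation = 0.95)
  s <- generate_session(cfg)
  bz <- bin_and_zscore(s$spikes, c(0, 900))
  n <- count_significant_patterns(bz)
  expect_equal(n, 1)
  pats <- extract_patterns(bz, n, seed = 1)
  expect_length(pats[[1]]$w, 40)
  expect_setequal(pats[[1]]$members, s$truth$assembly_memberships[[1]])
  # unit norm and sign convention
  expect_equal(sum(pats[[1]]$w^2), 1, tolerance = 1e-9)
  expect_gt(pats[[1]]$w[which.max(abs(pats[[1]]$w))], 0)
  # deterministic under a fixed seed
  pats2 <- extract_patterns(bz, n, seed = 1)
  expect_identical(pats[[1]]$w, pats2[[1]]$w)
})

test_that("theta comodulation adds a rank-two oscillatory subspace", {
  # phase-locked neurons with random preferred phases co-fluctuate through
  # the sin/cos components of the common rhythm: exactly two extra
  # eigenvalues cross the Marcenko-Pastur bound
  counts <- vapply(c(0, 0.8), function(kap) {
    cfg <- session_config(duration = 1200, n_pyr = 40, place_depth = 0,
                          theta_kappa = c(pyr = kap, msn = 0, fsi = 0,
                                          tan = 0),
                          seed = 23)
    s <- generate_session(cfg)
    count_significant_patterns(bin_and_zscore(s$spikes, c(0, 1200)))
  }, 0)
  expect_equal(counts[1], 0)
  expect_equal(counts[2], 2)
})

test_that("similarity obeys identity, orthogonality and sign invariance", {
  ids <- paste0("n", 1:6)
  w1 <- stats::setNames(c(1, 0, 0, 0, 0, 0), ids)
  w2 <- stats::setNames(c(0, 1, 0, 0, 0, 0), ids)
  p1 <- hpcnac:::new_assembly_pattern(w1)
  p2 <- hpcnac:::new_assembly_pattern(w2)
  p1neg <- hpcnac:::new_assembly_pattern(-w1 * c(-1))  # sign-fixed copy
  expect_equal(pattern_similarity(p1, p1), 1)
  expect_equal(pattern_similarity(p1, p2), 0)
  w3 <- stats::setNames(rep(1 / sqrt(6), 6), ids)
  p3 <- hpcnac:::new_assembly_pattern(w3)
  p3f <- structure(list(w = -w3, members = character()),
                   class = "assembly_pattern")
  expect_equal(pattern_similarity(p3, p3f), 1)
  expect_error(
    pattern_similarity(p1, hpcnac:::new_assembly_pattern(
      stats::setNames(1, "zz"))), "share no neurons")
})

test_that("cross-session matching recovers identity and permutations", {
  ids <- paste0("n", 1:8)
  set.seed(3)
  pats <- lapply(1:4, function(k) {
    w <- stats::rnorm(8); w <- w / sqrt(sum(w^2))
    if (w[which.max(abs(w))] < 0) w <- -w
    hpcnac:::new_assembly_pattern(stats::setNames(w, ids))
  })
  m_id <- match_patterns(pats, pats)
  expect_equal(m_id$matching$b[order(m_id$matching$a)], 1:4)
  expect_true(all(m_id$matching$similarity > 1 - 1e-9))
  perm <- c(3, 1, 4, 2)
  m_perm <- match_patterns(pats, pats[perm])
  got <- m_perm$matching$b[order(m_perm$matching$a)]
  expect_equal(perm[got], 1:4)
})

test_that("matched similarity on unrelated sessions falls to the shuffle null", {
  cfg_a <- recovery_config(seed = 41, n_pyr = 25, n_assemblies = 2,
                           members_per = 5, duration = 600)
  cfg_b <- recovery_config(seed = 42, n_pyr = 25, n_assemblies = 0,
                           members_per = 5, duration = 600)
  sa <- generate_session(cfg_a)
  sb <- generate_session(cfg_b)
  bza <- bin_and_zscore(sa$spikes, c(0, 600))
  pa <- extract_patterns(bza, count_significant_patterns(bza), seed = 1)
  self <- mean(match_patterns(pa, pa)$matching$similarity)
  # patterns "detected" on the unrelated session: random unit vectors from
  # shuffled weights serve as the independent comparison set
  shuf <- withr::with_seed(7, lapply(pa, function(p) {
    w <- sample(p$w)
    names(w) <- names(p$w)
    if (w[which.max(abs(w))] < 0) w <- -w
    hpcnac:::new_assembly_pattern(w)
  }))
  cross <- mean(match_patterns(pa, shuf)$matching$similarity)
  expect_equal(self, 1, tolerance = 1e-9)
  expect_lt(cross, self - 0.3)
})

test_that("activation strength matches the brute-force quadratic form", {
  w <- c(a = 0.6, b = 0.5, c = 0.4, d = 0.3, e = 0.3741657)
  w <- w / sqrt(sum(w^2))
  pat <- hpcnac:::new_assembly_pattern(w)
  trains <- poisson_trains(5, 10, 10, seed = 3)
  names(trains) <- names(w)
  at <- activation_strength(pat, trains, c(0, 10), step = 0.005)
  P <- hpcnac:::projector(pat)
  edges <- (0:2000) * 0.005
  Z <- t(vapply(names(w), function(id) {
    x <- hpcnac:::gauss_smooth(hpcnac:::bin_counts(trains[[id]], edges),
                               (0.025 / sqrt(12)) / 0.005)
    hpcnac:::zscore_pop(x)
  }, numeric(2000)))
  brute <- vapply(seq_len(ncol(Z)), function(j)
    as.numeric(t(Z[, j]) %*% P %*% Z[, j]), 0)
  expect_lt(max(abs(at$strength - brute)), 1e-9)
})

test_that("a single active neuron yields identically zero strength", {
  w <- stats::setNames(rep(1 / sqrt(5), 5), letters[1:5])
  pat <- hpcnac:::new_assembly_pattern(w)
  trains <- c(list(a = sort(stats::runif(50, 0, 10))),
              stats::setNames(replicate(4, numeric(), simplify = FALSE),
                              letters[2:5]))
  at <- suppressMessages(activation_strength(pat, trains, c(0, 10)))
  expect_true(all(at$strength == 0))
})

test_that("synchronous co-members peak positive, anti-correlated members negative", {
  w <- stats::setNames(c(1, 1) / sqrt(2), c("a", "b"))
  pat <- hpcnac:::new_assembly_pattern(w)
  sync <- list(a = seq(1, 9, by = 1), b = seq(1, 9, by = 1) + 0.002)
  at <- activation_strength(pat, sync, c(0, 10), step = 0.001)
  expect_gt(max(at$strength), 5)
  peak_t <- at$times[which.max(at$strength)]
  expect_lt(min(abs(peak_t - seq(1, 9))), 0.01)
  # never co-active: negative cross product at spike times
  anti <- list(a = seq(1, 9, by = 2), b = seq(2, 8, by = 2))
  at2 <- activation_strength(pat, anti, c(0, 10), step = 0.001)
  sp_idx <- vapply(c(anti$a, anti$b), function(s)
    which.min(abs(at2$times - s)), 0L)
  expect_true(all(at2$strength[sp_idx] <= 0))
})

test_that("activation detection respects threshold and local maxima", {
  tr <- structure(list(times = seq(0, 1, by = 0.001),
                       strength = rep(4.9, 1001), step = 0.001, r_thres = 5),
                  class = "activation_trace")
  expect_length(detect_activations(tr), 0)
  s <- rep(0, 1001); s[500] <- 5.1; s[499] <- 2; s[501] <- 2
  tr$strength <- s
  expect_length(detect_activations(tr), 1)
})

test_that("detected activations recover the embedded event times and rate", {
  cfg <- recovery_config(seed = 51, n_pyr = 30, n_assemblies = 1,
                         members_per = 6, duration = 600,
                         rate = 1, participation = 0.9)
  s <- generate_session(cfg)
  bz <- bin_and_zscore(s$spikes, c(0, 600))
  pats <- extract_patterns(bz, max(1, count_significant_patterns(bz)),
                           seed = 2)
  at <- activation_strength(pats[[1]], s$spikes, c(0, 600), step = 0.002)
  peaks <- detect_activations(at)
  ev <- s$truth$event_times[[1]]
  # peaks matched to embedded events (within one event window)
  matched <- sum(vapply(peaks, function(p)
    any(abs(ev + 0.0125 - p) <= 0.030), TRUE))
  expect_lt(abs(matched / 600 - length(ev) / 600) / (length(ev) / 600), 0.2)
})

test_that("activation rate is monotone in participation probability", {
  # at moderate background rates single-spike z-excursions sit below the
  # detection threshold, so the detected rate tracks participation
  rates <- vapply(c(0.3, 0.6, 0.9), function(p) {
    cfg <- session_config(
      duration = 600, n_pyr = 30, pyr_rate = 8, seed = 61, place_depth = 0,
      theta_kappa = c(pyr = 0, msn = 0, fsi = 0, tan = 0),
      assemblies = list(list(members = paste0("pyr", 1:6), rate = 1,
                             participation = p)))
    s <- generate_session(cfg)
    truth <- truth_patterns(s$truth$assembly_memberships,
                            names(s$spikes))[[1]]
    at <- activation_strength(truth, s$spikes, c(0, 600), step = 0.002)
    length(detect_activations(at)) / 600
  }, 0)
  expect_true(all(diff(rates) >= 0))
})

test_that("assembly maps localize peaks and conserve emptiness", {
  pos <- data.frame(t = seq(0, 99.96, by = 0.04),
                    x = rep(c(5, 45), each = 1250),
                    y = rep(5, 2500))
  peaks <- seq(10, 40, by = 1)  # animal at x=5 the whole time
  m <- assembly_map(peaks, pos, spatial_bin_cm = 10)
  nz <- which(m$counts > 0, arr.ind = TRUE)
  expect_equal(nrow(nz), 1)
  expect_equal(sum(m$counts), length(peaks))
  m0 <- assembly_map(numeric(), pos, spatial_bin_cm = 10)
  expect_true(all(m0$rate[!is.na(m0$rate)] == 0))
  expect_true(all(is.na(m0$rate[m0$occupancy == 0])))
})
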