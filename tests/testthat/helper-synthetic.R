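# Shared fixtures, all generated in code.

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# Independent homogeneous Poisson spike trains (no generator machinery).
poisson_trains <- function(n_neurons, rate, duration, seed) {
  withr::with_seed(seed, {
    tr <- lapply(seq_len(n_neurons), function(i)
      sort(stats::runif(stats::rpois(1, rate * duration), 0, duration)))
    names(tr) <- paste0("n", seq_len(n_neurons))
    tr
  })
}

# Unmodulated background with embedded assemblies: the recovery benchmark
# isolates assembly structure by switching off theta/place comodulation.
recovery_config <- function(seed, n_pyr = 50, n_assemblies = 5,
                            members_per = 6, duration = 1200,
                            rate = 1, participation = 0.8) {
  members <- lapply(seq_len(n_assemblies), function(k)
    paste0("pyr", ((k - 1) * members_per + 1):(k * members_per)))
  session_config(
    duration = duration, n_pyr = n_pyr, seed = seed,
    place_depth = 0,
    theta_kappa = c(pyr = 0, msn = 0, fsi = 0, tan = 0),
    assemblies = lapply(members, function(m)
      list(members = m, rate = rate, participation = participation))
  )
}

truth_patterns <- function(members, all_ids) {
  lapply(members, function(m) {
    w <- stats::setNames(rep(0, length(all_ids)), all_ids)
    w[m] <- 1 / sqrt(length(m))
    structure(list(w = w, members = m), class = "assembly_pattern")
  })
}

# One synthetic PYR-FSI pair, theta-comodulated, optionally monosynaptically
# coupled; returns the short-latency surrogate-band exceedance verdict.
pair_exceeds_band <- function(seed, coupled, duration = 300,
                              n_surrogates = 200) {
  cfg <- session_config(
    duration = duration, n_pyr = 1, n_fsi = 1, pyr_rate = 4, fsi_rate = 10,
    place_depth = 0, theta_kappa = c(pyr = 1, msn = 0, fsi = 1, tan = 0),
    couplings = if (coupled)
      data.frame(pre = "pyr1", post = "fsi1", latency_ms = 4, efficacy = 0.2)
    else NULL,
    seed = seed
  )
  s <- generate_session(cfg)
  ccg <- cross_correlogram(s$spikes$pyr1, s$spikes$fsi1,
                           window_s = 0.2, bin_s = 0.001,
                           cycles = s$cycles, n_surrogates = n_surrogates,
                           global_window_ms = c(3.2, 8),
                           seed = seed + 10000L)
  ccg$global_exceeds
}

# Cycle-count sessions for the ensemble-prediction tests: PYR population
# drives one MSN through known linear coupling (extra MSN spikes triggered by
# specific PYRs).
glm_session <- function(seed, efficacies, duration = 200) {
  n_pyr <- length(efficacies)
  cfg <- session_config(
    duration = duration, n_pyr = n_pyr, n_msn = 1,
    pyr_rate = 3, msn_rate = 1, place_depth = 0,
    theta_kappa = c(pyr = 0.6, msn = 0.2, fsi = 0, tan = 0),
    couplings = if (any(efficacies > 0)) data.frame(
      pre = paste0("pyr", which(efficacies > 0)),
      post = "msn1",
      latency_ms = 6,
      efficacy = efficacies[efficacies > 0]
    ) else NULL,
    seed = seed
  )
  s <- generate_session(cfg)
  bin_by_cycles(s$spikes, s$cycles)
}

vm_phases <- function(n, kappa, seed) {
  withr::with_seed(seed, {
    if (kappa == 0) return(stats::runif(n, 0, 2 * pi))
    out <- numeric(0)
    while (length(out) < n) {
      cand <- stats::runif(n, 0, 2 * pi)
      keep <- stats::runif(n) < exp(kappa * (cos(cand) - 1))
      out <- c(out, cand[keep])
    }
    out[seq_len(n)]
  })
}
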