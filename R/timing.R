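#' Spike-time cross-correlogram
#'
#' For every reference spike, target spikes are binned by lag within
#' `[-window_s, window_s]`; counts are divided by the number of reference
#' spikes, giving the target discharge probability per lag bin. Optionally a
#' theta-phase-preserving surrogate band is attached (see
#' [theta_shift_surrogates]).
#'
#' @param ref,target spike-time vectors, seconds (both non-empty).
#' @param window_s half-width of the lag window, seconds (default 0.2).
#' @param bin_s lag bin width, seconds (default 1 ms).
#' @param cycles optional [theta_cycles]; with `n_surrogates > 0`, reference
#'   spikes are shifted to random cycles at preserved phase and the per-bin
#'   surrogate quantile band is attached.
#' @param n_surrogates number of surrogate shift controls.
#' @param band_quantiles lower/upper band quantiles (default 0.5% / 99.5%).
#' @param global_window_ms optional `c(lo, hi)` lag window (ms): additionally
#'   computes a simultaneous ("global") band over that window from the
#'   per-surrogate maximum bin probability, the standard control of
#'   family-wise error when testing a short-latency window against a
#'   surrogate null.
#' @param seed integer seed for the surrogates.
#' @return object of class `correlogram`: data frame fields `lag_ms`, `prob`
#'   plus `n_ref`, `bin_ms`, and optionally `band_lo`, `band_hi`,
#'   `band_mean`; with `global_window_ms` also `global_hi` (simultaneous
#'   upper bound) and `global_exceeds` (whether any original bin in the
#'   window exceeds it).
#' @export
cross_correlogram <- function(ref, target, window_s = 0.2, bin_s = 0.001,
                              cycles = NULL, n_surrogates = 0,
                              band_quantiles = c(0.005, 0.995),
                              global_window_ms = NULL, seed = 1) {
  ref <- sort(ref); target <- sort(target)
  if (!length(ref) || !length(target)) stop("both spike trains must be non-empty")
  edges <- seq(-window_s, window_s, by = bin_s)
  cnt <- ccg_counts(ref, target, edges)
  out <- list(lag_ms = 1000 * (edges[-length(edges)] + bin_s / 2),
              prob = cnt / length(ref),
              n_ref = length(ref), bin_ms = 1000 * bin_s)
  if (!is.null(cycles) && n_surrogates > 0) {
    surr <- theta_shift_surrogates(ref, cycles, n = n_surrogates, seed = seed)
    mat <- matrix(0, n_surrogates, length(edges) - 1)
    for (s in seq_len(n_surrogates))
      mat[s, ] <- ccg_counts(surr[[s]], target, edges) / length(surr[[s]])
    out$band_lo <- apply(mat, 2, quantile, probs = band_quantiles[1])
    out$band_hi <- apply(mat, 2, quantile, probs = band_quantiles[2])
    out$band_mean <- colMeans(mat)
    if (!is.null(global_window_ms)) {
      win <- out$lag_ms > global_window_ms[1] & out$lag_ms <= global_window_ms[2]
      if (!any(win)) stop("global window contains no lag bins")
      maxes <- apply(mat[, win, drop = FALSE], 1, max)
      out$global_hi <- unname(quantile(maxes, probs = band_quantiles[2]))
      out$global_exceeds <- any(out$prob[win] > out$global_hi)
    }
  }
  structure(out, class = "correlogram")
}

# Vectorized lag binning: counts of (ref, target) lag pairs per bin.
ccg_counts <- function(ref, target, edges) {
  lo <- findInterval(ref + edges[1], target)
  hi <- findInterval(ref + edges[length(edges)], target)
  m <- hi - lo
  use <- m > 0
  if (!any(use)) return(numeric(length(edges) - 1))
  pos <- sequence(m[use]) + rep(lo[use], m[use])
  lags <- round(target[pos] - rep(ref[use], m[use]), 9)  # snap float jitter
  lags <- lags[lags >= edges[1] & lags < edges[length(edges)]]
  tabulate(findInterval(lags, edges), nbins = length(edges) - 1)
}

#' Population cross-correlogram over many cell pairs
#'
#' Either averages the per-pair discharge probabilities (default) or pools
#' spikes across pairs before normalizing by the total reference count. The
#' two conventions differ when pairs contribute unequal spike counts; both
#' are exposed because published population correlograms rarely state which
#' was used.
#'
#' @param pairs list of `list(ref =, target =)` spike-train pairs.
#' @param mode `"average"` or `"pooled"`.
#' @inheritParams cross_correlogram
#' @return a `correlogram` object.
#' @export
population_correlogram <- function(pairs, window_s = 0.2, bin_s = 0.001,
                                   mode = c("average", "pooled")) {
  mode <- match.arg(mode)
  edges <- seq(-window_s, window_s, by = bin_s)
  probs <- NULL; total_cnt <- 0; total_ref <- 0
  for (p in pairs) {
    cnt <- ccg_counts(sort(p$ref), sort(p$target), edges)
    if (mode == "average") {
      pr <- cnt / length(p$ref)
      probs <- if (is.null(probs)) pr else probs + pr
    } else {
      total_cnt <- total_cnt + cnt
      total_ref <- total_ref + length(p$ref)
    }
  }
  prob <- if (mode == "average") probs / length(pairs) else total_cnt / total_ref
  structure(list(lag_ms = 1000 * (edges[-length(edges)] + bin_s / 2),
                 prob = prob,
                 n_ref = if (mode == "pooled") total_ref else NA_integer_,
                 bin_ms = 1000 * bin_s),
            class = "correlogram")
}

#' Theta-phase-preserving shift surrogates
#'
#' Builds null spike trains that destroy fine (millisecond) spike timing
#' while preserving theta-phase statistics exactly: each spike is relocated
#' to an independently chosen random valid theta cycle, at the time within
#' that cycle whose phase equals the spike's original phase (phase-to-time by
#' the cycle's linear phase map). Every surrogate therefore has the same
#' spike count and the same phase multiset as the original train.
#'
#' @param spikes reference spike times, seconds. Spikes outside cycle
#'   coverage (or in flagged cycles) are excluded with a warning.
#' @param cycles a [theta_cycles] object.
#' @param n number of surrogates.
#' @param seed integer seed.
#' @return list of `n` sorted surrogate spike-time vectors.
#' @export
theta_shift_surrogates <- function(spikes, cycles, n = 1000, seed = 1) {
  idx <- cycle_index(cycles, spikes)
  ok <- !is.na(idx) & cycles$valid[pmax(idx, 1L)]
  if (any(!ok)) {
    warning(sum(!ok), " spike(s) outside covered theta cycles excluded")
    spikes <- spikes[ok]
  }
  if (!length(spikes)) stop("no spikes within covered theta cycles")
  ph <- phase_at(cycles, spikes)
  valid_cycles <- which(cycles$valid)
  withr::with_seed(seed, {
    lapply(seq_len(n), function(s) {
      cyc <- valid_cycles[sample.int(length(valid_cycles), length(spikes),
                                     replace = TRUE)]
      sort(time_of_phase(cycles, cyc, ph))
    })
  })
}

#' Light-driven firing-rate score
#'
#' `(r_ON - r_OFF) / (r_ON + r_OFF)`: -1 for complete suppression during
#' light, 0 for no change, +1 for firing only during light. The same formula
#' applied to the two flanking OFF epochs serves as the no-light control.
#'
#' @param spikes spike times, seconds.
#' @param on_epochs,off_epochs epoch tables with columns `start`, `end`
#'   (seconds), both non-empty.
#' @return score in `[-1, 1]`, or `NA` (with a message) when the unit never
#'   fires in either epoch set.
#' @export
light_rate_score <- function(spikes, on_epochs, off_epochs) {
  r_on <- epoch_rate(spikes, on_epochs)
  r_off <- epoch_rate(spikes, off_epochs)
  if (r_on + r_off == 0) {
    message("unit fires in neither epoch set; score undefined")
    return(NA_real_)
  }
  (r_on - r_off) / (r_on + r_off)
}

epoch_rate <- function(spikes, epochs) {
  epochs <- as.data.frame(epochs)
  stopifnot(nrow(epochs) > 0, all(c("start", "end") %in% names(epochs)))
  n <- 0; total <- 0
  for (i in seq_len(nrow(epochs))) {
    n <- n + sum(spikes >= epochs$start[i] & spikes < epochs$end[i])
    total <- total + (epochs$end[i] - epochs$start[i])
  }
  n / total
}

#' Kernel density of rate scores
#'
#' Gaussian kernel density estimate over the score range `[-1, 1]`, with the
#' bandwidth set by Silverman's rule clipped to `[0.02, 0.2]` on the score
#' scale, renormalized to integrate to 1 over the evaluation grid.
#'
#' @param scores finite rate scores (>= 2).
#' @param bandwidth optional override of the kernel SD.
#' @param n_grid number of evaluation points.
#' @return data frame `score`, `density`.
#' @export
score_density <- function(scores, bandwidth = NULL, n_grid = 512) {
  scores <- scores[is.finite(scores)]
  if (length(scores) < 2) stop("need at least two finite scores")
  if (is.null(bandwidth)) {
    bandwidth <- stats::bw.nrd0(scores)
    bandwidth <- min(max(bandwidth, 0.02), 0.2)
  }
  d <- density(scores, bw = bandwidth, from = -1, to = 1, n = n_grid)
  dx <- diff(d$x[1:2])
  area <- sum(d$y) * dx
  data.frame(score = d$x, density = d$y / area)
}

#' Theta modulation depth (Rayleigh vector length)
#'
#' Modulus of the mean unit phasor over the theta phases of all spikes
#' within cycle coverage: 1 for perfect phase locking, near 0 for uniform
#' phases.
#'
#' @param spikes spike times, seconds.
#' @param cycles a [theta_cycles] object (or precomputed phases in radians
#'   via `phases`).
#' @param phases optional spike phases in radians, bypassing `cycles`.
#' @return Rayleigh vector length in `[0, 1]`.
#' @export
theta_modulation_depth <- function(spikes = NULL, cycles = NULL, phases = NULL) {
  if (is.null(phases)) {
    phases <- phase_at(cycles, spikes)
    phases <- phases[!is.na(phases)]
  }
  if (!length(phases)) stop("no spikes within phase coverage")
  Mod(mean(exp(1i * phases)))
}

#' Kinetics of an average postsynaptic potential
#'
#' Detects the synaptic event as the first upward deflection exceeding the
#' pre-stimulus baseline mean by more than `k_sd` baseline SDs, and measures
#' its peak amplitude (relative to baseline), duration (between threshold
#' crossings), and 20-80% rise time (linear interpolation on the rising
#' limb). With two stimulus times the paired-pulse ratio is the second
#' event's amplitude over the first's.
#'
#' @param t,v time (seconds) and voltage samples of the average trace.
#' @param baseline `c(start, end)` of the pre-stimulus baseline window.
#' @param stim_times optional stimulus onset times; events are measured in
#'   each inter-stimulus segment.
#' @param k_sd event criterion in baseline SDs (default 2).
#' @return list `events` (data frame `amplitude, duration, rise_time, onset,
#'   peak_time`, one row per detected event), `ppr` (second/first amplitude,
#'   `NA` unless two events), `baseline_mean`, `baseline_sd`. A trace with no
#'   supra-threshold deflection yields zero event rows.
#' @export
psp_kinetics <- function(t, v, baseline, stim_times = NULL, k_sd = 2) {
  stopifnot(length(t) == length(v), baseline[1] < baseline[2])
  bi <- t >= baseline[1] & t < baseline[2]
  if (!any(bi)) stop("baseline window contains no samples")
  bm <- mean(v[bi]); bs <- stats::sd(v[bi])
  if (is.na(bs)) bs <- 0
  thr <- bm + k_sd * bs

  segments <- if (is.null(stim_times)) {
    list(c(baseline[2], max(t)))
  } else {
    stim_times <- sort(stim_times)
    lapply(seq_along(stim_times), function(i) {
      c(stim_times[i],
        if (i < length(stim_times)) stim_times[i + 1] else max(t))
    })
  }

  one_event <- function(win) {
    si <- which(t >= win[1] & t <= win[2])
    if (length(si) < 3) return(NULL)
    st <- t[si]; sv <- v[si]
    above <- sv > thr
    if (!any(above)) return(NULL)
    i0 <- which(above)[1]
    run_end <- i0
    while (run_end < length(sv) && sv[run_end + 1] > thr) run_end <- run_end + 1
    onset <- if (i0 > 1) {
      approx(sv[(i0 - 1):i0], st[(i0 - 1):i0], xout = thr)$y
    } else st[1]
    offset <- if (run_end < length(sv)) {
      approx(sv[run_end:(run_end + 1)], st[run_end:(run_end + 1)], xout = thr)$y
    } else st[length(st)]
    pk <- i0 - 1 + which.max(sv[i0:run_end])
    amp <- sv[pk] - bm
    rise_lo <- bm + 0.2 * amp
    rise_hi <- bm + 0.8 * amp
    limb <- si[1]:(si[1] + pk - 1)
    t20 <- crossing_time(t[limb], v[limb], rise_lo)
    t80 <- crossing_time(t[limb], v[limb], rise_hi)
    data.frame(amplitude = amp, duration = offset - onset,
               rise_time = t80 - t20, onset = onset, peak_time = st[pk])
  }

  events <- do.call(rbind, Filter(Negate(is.null), lapply(segments, one_event)))
  if (is.null(events))
    events <- data.frame(amplitude = numeric(), duration = numeric(),
                         rise_time = numeric(), onset = numeric(),
                         peak_time = numeric())
  ppr <- if (nrow(events) >= 2) events$amplitude[2] / events$amplitude[1]
         else NA_real_
  list(events = events, ppr = ppr, baseline_mean = bm, baseline_sd = bs)
}

# Last upward crossing of `level` before the maximum, linear interpolation.
crossing_time <- function(t, v, level) {
  pk <- which.max(v)
  below <- which(v[seq_len(pk)] < level)
  if (!length(below)) return(t[1])
  i <- max(below)
  if (i >= pk) return(t[pk])
  approx(v[i:(i + 1)], t[i:(i + 1)], xout = level, ties = "ordered")$y
}
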