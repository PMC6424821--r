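#' Theta-cycle container
#'
#' Ordered cycle boundaries plus a piecewise-linear phase map. Cycle `i` spans
#' the half-open interval `[boundaries[i], boundaries[i+1])`; phase is 0 at
#' each boundary and grows linearly to `2*pi` at the next one. Cycles whose
#' length falls outside the theta band (4-12 Hz, i.e. 83-250 ms) are flagged
#' invalid and skipped by downstream consumers (surrogates, cycle binning).
#'
#' @param boundaries strictly increasing numeric vector of cycle-start times
#'   (seconds); the last element closes the final cycle.
#' @param band permissible cycle-frequency band in Hz.
#' @return an object of class `theta_cycles` with elements `boundaries`,
#'   `lengths` and logical `valid`.
#' @export
theta_cycles <- function(boundaries, band = c(4, 12)) {
  boundaries <- as.numeric(boundaries)
  if (length(boundaries) < 2) stop("need at least two boundaries (one cycle)")
  if (any(diff(boundaries) <= 0)) stop("boundaries must be strictly increasing")
  len <- diff(boundaries)
  valid <- len >= 1 / band[2] & len <= 1 / band[1]
  structure(
    list(boundaries = boundaries, lengths = len, valid = valid, band = band),
    class = "theta_cycles"
  )
}

#' @export
print.theta_cycles <- function(x, ...) {
  cat(sprintf(
    "<theta_cycles> %d cycles over [%.3f, %.3f] s; median length %.1f ms; %d flagged\n",
    length(x$lengths), x$boundaries[1], tail(x$boundaries, 1),
    1000 * stats::median(x$lengths), sum(!x$valid)
  ))
  invisible(x)
}

n_cycles <- function(cycles) length(cycles$lengths)

#' Instantaneous theta phase at given times
#'
#' @param cycles a [theta_cycles] object.
#' @param t numeric times (seconds).
#' @return phases in `[0, 2*pi)`; `NA` outside cycle coverage.
#' @export
phase_at <- function(cycles, t) {
  b <- cycles$boundaries
  idx <- findInterval(t, b)
  out <- rep(NA_real_, length(t))
  ok <- idx >= 1 & idx <= length(cycles$lengths)
  out[ok] <- 2 * pi * (t[ok] - b[idx[ok]]) / cycles$lengths[idx[ok]]
  out
}

# Inverse phase map: the time within cycle `cycle_idx` at which the phase
# equals `phase` (linear interpolation of the cycle's phase ramp).
time_of_phase <- function(cycles, cycle_idx, phase) {
  cycles$boundaries[cycle_idx] + (phase / (2 * pi)) * cycles$lengths[cycle_idx]
}

# Index of the cycle containing each time (NA outside coverage).
cycle_index <- function(cycles, t) {
  idx <- findInterval(t, cycles$boundaries)
  idx[idx < 1 | idx > length(cycles$lengths)] <- NA_integer_
  idx
}

#' Segment a phase or LFP series into theta cycles
#'
#' If an analytic phase series is supplied, cycle boundaries are placed at the
#' wrapped-phase zero crossings (sub-sample, by linear interpolation of the
#' unwrapped phase). If a raw LFP trace is supplied it is band-pass filtered
#' (3rd-order Butterworth, forward-backward) and the instantaneous phase taken
#' from the analytic signal. Cycles outside 83-250 ms are flagged invalid.
#'
#' @param x numeric series: instantaneous phase in radians (`type = "phase"`)
#'   or a raw LFP trace (`type = "lfp"`), uniformly sampled.
#' @param fs sampling rate in Hz.
#' @param band theta band in Hz (default 4-12).
#' @param type `"phase"` or `"lfp"`.
#' @param t0 time of the first sample (seconds).
#' @return a [theta_cycles] object.
#' @export
detect_theta_cycles <- function(x, fs, band = c(4, 12), type = c("phase", "lfp"),
                                t0 = 0) {
  type <- match.arg(type)
  if (length(x) < fs / band[1]) stop("series shorter than one theta cycle")
  tgrid <- t0 + (seq_along(x) - 1) / fs
  if (type == "lfp") {
    bf <- signal::butter(3, band / (fs / 2), type = "pass")
    xf <- signal::filtfilt(bf, x - mean(x))
    phase <- Arg(analytic_signal(xf))
  } else {
    phase <- x
  }
  # unwrap, then place boundaries where the unwrapped phase crosses 2*pi*k
  d <- diff(phase)
  d <- ((d + pi) %% (2 * pi)) - pi
  u <- cumsum(c(phase[1], d))
  ks <- seq(ceiling(min(u) / (2 * pi)), floor(max(u) / (2 * pi)))
  if (length(ks) < 2) stop("series shorter than one theta cycle")
  bnd <- approx(u, tgrid, xout = 2 * pi * ks, ties = "ordered")$y
  # filter and Hilbert edge transients contaminate the outermost cycles of a
  # raw LFP trace; drop them when enough cycles remain
  if (type == "lfp" && length(bnd) >= 4) bnd <- bnd[2:(length(bnd) - 1)]
  theta_cycles(bnd, band = band)
}

# Analytic signal via the frequency-domain Hilbert construction.
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(fft(x) * h, inverse = TRUE) / n
}

# Analytic theta phase generator: constant nominal frequency with optional
# per-cycle length jitter; returns exact boundaries so cycle detection can be
# bypassed or validated against truth.
make_theta_cycles <- function(duration, freq = 8, cycle_jitter = 0, seed = 1) {
  withr::with_seed(seed, {
    n <- ceiling(duration * freq * 1.2) + 2L
    len <- (1 / freq) * (1 + cycle_jitter * stats::runif(n, -1, 1))
    b <- c(0, cumsum(len))
    b <- b[b <= duration + 1 / freq]
    if (length(b) < 2) b <- c(0, 1 / freq)
    theta_cycles(b)
  })
}
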