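#' @importFrom stats rpois runif rnorm sd quantile approx cor density kmeans
#'   hclust cutree dist lm.fit glm.fit poisson fft convolve rexp
#' @importFrom utils head tail
NULL

# Deterministic substream seeds: one master seed, independent 32-bit streams
# keyed by stage/neuron label so adding streams never perturbs existing ones.
substream_seed <- function(seed, key) {
  h <- 0
  for (ch in utf8ToInt(as.character(key))) h <- (h * 31 + ch) %% 2147483647
  as.integer((abs(as.numeric(seed)) * 48271 + h * 1009 + 12345) %% 2147483647)
}

# z-score with population SD (denominator n, not n-1); rows of binned count
# matrices must come out with SD exactly 1 under this convention.
zscore_pop <- function(x) {
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s == 0) stop("zero-variance vector cannot be z-scored")
  (x - m) / s
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Bin spike times onto a uniform grid
#'
#' Counts spikes in half-open bins `[edges[k], edges[k+1])`.
#' @keywords internal
bin_counts <- function(times, edges) {
  times <- times[times >= edges[1] & times < edges[length(edges)]]
  if (!length(times)) return(integer(length(edges) - 1L))
  idx <- findInterval(times, edges, rightmost.closed = FALSE)
  tabulate(idx, nbins = length(edges) - 1L)
}

# Gaussian smoothing of a regularly sampled series (direct FIR convolution,
# kernel truncated at 5 SD, zero-padded edges). Same length as input.
gauss_smooth <- function(x, sd_samples) {
  if (sd_samples <= 0) return(x)
  half <- max(1L, ceiling(5 * sd_samples))
  k <- exp(-0.5 * ((-half:half) / sd_samples)^2)
  k <- k / sum(k)
  n <- length(x)
  xp <- c(rep(0, half), x, rep(0, half))
  y <- stats::filter(xp, k, method = "convolution", sides = 2)
  as.numeric(y[(half + 1):(half + n)])
}

# Canonical spike-train container: named list of sorted numeric vectors.
as_spike_trains <- function(spikes) {
  if (inherits(spikes, "spike_trains")) return(spikes)
  if (is.data.frame(spikes)) {
    stopifnot(all(c("neuron_id", "time") %in% names(spikes)))
    out <- split(spikes$time, as.character(spikes$neuron_id))
    out <- lapply(out, sort)
  } else if (is.list(spikes)) {
    stopifnot(!is.null(names(spikes)))
    out <- lapply(spikes, function(v) sort(as.numeric(v)))
  } else if (is.numeric(spikes)) {
    out <- list(unit = sort(spikes))
  } else {
    stop("cannot interpret 'spikes' as spike trains")
  }
  structure(out, class = "spike_trains")
}

spikes_to_df <- function(trains) {
  trains <- as_spike_trains(trains)
  data.frame(
    neuron_id = rep(names(trains), lengths(trains)),
    time = unlist(trains, use.names = FALSE),
    stringsAsFactors = FALSE
  )
}
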