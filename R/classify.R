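#' Mean spike waveform from aligned snippets
#'
#' Upsamples each channel's spike snippets to 40 kHz (linear interpolation),
#' aligns every snippet to its maximal trough, averages per channel, and
#' returns the average of the channel with the largest peak-to-peak
#' amplitude, with the trough placed at t = 0.
#'
#' @param snippets a matrix (snippets x samples) for a single channel, or a
#'   list of such matrices (one per tetrode channel).
#' @param fs sampling rate of the snippets, Hz.
#' @param fs_out output sampling rate, Hz (default 40 kHz).
#' @return list `w` (mean waveform), `t_ms` (sample times, trough at 0),
#'   `channel` (index of the selected channel), `fs`.
#' @export
mean_waveform <- function(snippets, fs, fs_out = 40000) {
  if (is.matrix(snippets)) snippets <- list(snippets)
  if (!length(snippets) || any(!vapply(snippets, nrow, 0L)))
    stop("need at least one spike snippet per channel")
  up <- max(1L, round(fs_out / fs))
  avg_channel <- function(m) {
    n_in <- ncol(m)
    n_out <- (n_in - 1L) * up + 1L
    x_in <- seq_len(n_in)
    x_out <- seq(1, n_in, length.out = n_out)
    um <- t(apply(m, 1, function(r) approx(x_in, r, xout = x_out)$y))
    # align each snippet's trough to the median trough position
    troughs <- apply(um, 1, which.min)
    ref <- round(stats::median(troughs))
    aligned <- matrix(NA_real_, nrow(um), n_out)
    for (i in seq_len(nrow(um))) {
      sh <- ref - troughs[i]
      src <- seq_len(n_out) - sh
      ok <- src >= 1 & src <= n_out
      aligned[i, which(ok)] <- um[i, src[ok]]
    }
    colMeans(aligned, na.rm = TRUE)
  }
  means <- lapply(snippets, avg_channel)
  amp <- vapply(means, function(w) diff(range(w)), 0)
  best <- which.max(amp)
  w <- means[[best]]
  trough <- which.min(w)
  t_ms <- (seq_along(w) - trough) * 1000 / (fs * up)
  list(w = w, t_ms = t_ms, channel = best, fs = fs * up)
}

#' Waveform shape features for cell-type classification
#'
#' Parameterizes a mean waveform `w(t)` (trough at t = 0) by three measures:
#' the duration of the first peak (time from the trough to the second zero
#' intercept on its left — the far edge of the positive peak preceding the
#' trough), the duration of the second peak (second zero intercept to the
#' right), and the spike symmetry — the amplitude of the first (left) peak
#' over the sum of the first and second peak amplitudes. Zero intercepts are
#' located by linear interpolation between samples. All three features are
#' invariant to positive rescaling of the waveform.
#'
#' @param w numeric waveform samples.
#' @param t_ms sample times in ms with the trough at 0 (computed from the
#'   global minimum if omitted and `fs` given).
#' @param fs sampling rate in Hz, used when `t_ms` is missing.
#' @return list `first_peak_ms`, `second_peak_ms`, `symmetry`; or an error of
#'   class `hpcnac_feature_error` when the required zero intercepts are
#'   missing (unit unclassifiable).
#' @export
waveform_features <- function(w, t_ms = NULL, fs = NULL) {
  if (is.null(t_ms)) {
    if (is.null(fs)) stop("supply t_ms or fs")
    t_ms <- (seq_along(w) - which.min(w)) * 1000 / fs
  }
  trough <- which.min(w)
  if (sum(w == w[trough]) > 1)
    stop_feature("waveform has no unique global minimum")
  zc <- zero_crossings(w, t_ms)
  left <- rev(zc[zc < 0])
  right <- zc[zc > 0]
  if (length(left) < 2 || length(right) < 2)
    stop_feature("waveform lacks two zero intercepts on each side of the trough")
  first_peak_ms <- abs(left[2])
  second_peak_ms <- right[2]
  amp1 <- max(w[t_ms >= left[2] & t_ms <= left[1]])
  amp2 <- max(w[t_ms >= right[1] & t_ms <= right[2]])
  if (amp1 + amp2 <= 0) stop_feature("flanking peaks have nonpositive amplitude")
  list(first_peak_ms = first_peak_ms, second_peak_ms = second_peak_ms,
       symmetry = amp1 / (amp1 + amp2))
}

stop_feature <- function(msg) {
  stop(structure(class = c("hpcnac_feature_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# Times where the waveform crosses zero, by linear interpolation.
zero_crossings <- function(w, t_ms) {
  s <- sign(w)
  idx <- which(s[-1] * s[-length(s)] < 0)
  t_ms[idx] - w[idx] * (t_ms[idx + 1] - t_ms[idx]) / (w[idx + 1] - w[idx])
}

#' Classify striatal units from waveform features
#'
#' Z-scales the three waveform features and partitions the units with
#' k-means (k = 3, seeded, multi-restart). Clusters are mapped to cell types
#' by physiology: the cluster with the briefest spikes (smallest mean summed
#' peak durations) is FSI; of the remaining two, the one with the lower mean
#' firing rate is MSN, the other TAN. The partition is cross-checked with
#' DBSCAN (epsilon from the knee of the k-distance curve, k = 4) and
#' Ward-linkage hierarchical clustering; pairwise adjusted Rand indices
#' are reported alongside per-unit silhouette widths. DBSCAN runs with
#' `min_pts = 8` at typical unit counts (shrinking to 4 below 100 units),
#' large enough to suppress spurious density bridges between
#' adjacent clusters; its noise points are attached
#' to the nearest clustered point for the agreement comparison (the raw
#' partition is also returned).
#'
#' @param features data frame or matrix with columns `first_peak_ms`,
#'   `second_peak_ms`, `symmetry`, one row per unit.
#' @param rates mean firing rate (Hz) per unit, used only to name clusters.
#' @param seed integer seed for k-means restarts.
#' @return list `labels` (factor FSI/MSN/TAN per unit), `silhouette`
#'   (per-unit width), `agreement` (adjusted Rand: kmeans-dbscan,
#'   kmeans-hclust, dbscan-hclust), `kmeans`, `dbscan`, `hclust` (raw
#'   cluster indices).
#' @export
classify_units <- function(features, rates, seed = 1) {
  X <- as.matrix(as.data.frame(features)[, c("first_peak_ms", "second_peak_ms",
                                             "symmetry")])
  n <- nrow(X)
  if (n < 3) stop("need at least three units with defined features")
  if (any(apply(X, 2, stats::sd) == 0))
    stop("degenerate identical features; cannot cluster")
  Xs <- scale(X)
  km <- withr::with_seed(seed, kmeans(Xs, centers = 3, nstart = 25,
                                      iter.max = 100))
  dur <- X[, "first_peak_ms"] + X[, "second_peak_ms"]
  mean_dur <- tapply(dur, km$cluster, mean)
  fsi_cl <- as.integer(names(which.min(mean_dur)))
  rest <- setdiff(1:3, fsi_cl)
  mean_rate <- tapply(rates, km$cluster, mean)
  msn_cl <- rest[which.min(mean_rate[as.character(rest)])]
  tan_cl <- setdiff(rest, msn_cl)
  lab_map <- character(3)
  lab_map[fsi_cl] <- "FSI"; lab_map[msn_cl] <- "MSN"; lab_map[tan_cl] <- "TAN"
  labels <- factor(lab_map[km$cluster], levels = c("FSI", "MSN", "TAN"))

  min_pts <- max(4L, min(8L, floor(n / 25)))
  db_raw <- dbscan_simple(Xs, eps = kdist_knee(Xs, k = 4), min_pts = min_pts)
  db <- assign_noise_to_nearest(Xs, db_raw)
  hc <- cutree(hclust(dist(Xs), method = "ward.D2"), k = 3)
  sil <- cluster::silhouette(km$cluster, dist(Xs))[, "sil_width"]
  agreement <- c(
    kmeans_dbscan = mclust::adjustedRandIndex(km$cluster, db),
    kmeans_hclust = mclust::adjustedRandIndex(km$cluster, hc),
    dbscan_hclust = mclust::adjustedRandIndex(db, hc)
  )
  list(labels = labels, silhouette = sil, agreement = agreement,
       kmeans = km$cluster, dbscan = db, dbscan_raw = db_raw, hclust = hc)
}

# DBSCAN noise points are attached to the nearest clustered point so the
# cross-algorithm agreement compares full partitions.
assign_noise_to_nearest <- function(X, cl) {
  if (!any(cl == 0) || max(cl) == 0) return(cl)
  D <- as.matrix(dist(X))
  clustered <- which(cl > 0)
  for (i in which(cl == 0)) cl[i] <- cl[clustered[which.min(D[i, clustered])]]
  cl
}

# Minimal DBSCAN (no installed implementation in this stack): O(n^2) distance
# queries, fine for unit counts in the hundreds. Noise points get cluster 0.
dbscan_simple <- function(X, eps, min_pts = 4) {
  n <- nrow(X)
  D <- as.matrix(dist(X))
  neighbors <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- vapply(neighbors, length, 0L) >= min_pts
  cl <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (cl[i] != 0L || !core[i]) next
    cur <- cur + 1L
    queue <- i
    cl[i] <- cur
    while (length(queue)) {
      j <- queue[1]; queue <- queue[-1]
      for (k in neighbors[[j]]) {
        if (cl[k] == 0L) {
          cl[k] <- cur
          if (core[k]) queue <- c(queue, k)
        }
      }
    }
  }
  cl
}

# Epsilon heuristic: the knee (the point farthest from the chord) of the
# sorted k-nearest-neighbor distance curve.
kdist_knee <- function(X, k = 4) {
  D <- as.matrix(dist(X))
  kd <- sort(apply(D, 1, function(r) sort(r)[k + 1]))
  n <- length(kd)
  x <- seq_len(n)
  chord <- kd[1] + (kd[n] - kd[1]) * (x - 1) / (n - 1)
  kd[which.max(abs(kd - chord))]
}

#' Opto-tagging from pulse-aligned spike probability
#'
#' Builds a peri-pulse spike-probability histogram (0.2-ms bins) and tags the
#' unit when any bin in the response window (0, 8] ms exceeds the baseline
#' mean by more than `k` baseline SDs (baseline = [-50, 0) ms before pulse
#' onset). The tag latency is the center of the first supra-threshold bin.
#' When the baseline is silent its SD is floored at the binomial SD of half a
#' spike over the pulse count, so a silent baseline cannot tag by division
#' blow-up.
#'
#' @param spikes spike times of one unit, seconds.
#' @param pulses light-pulse onset times, seconds (>= 50 pulses).
#' @param bin_ms PSTH bin width, ms.
#' @param window_ms response window after pulse onset, ms.
#' @param baseline_ms baseline window before pulse onset, ms.
#' @param k SD multiplier for the tagging threshold.
#' @return list `tagged`, `latency_ms` (NA when untagged), `psth` (data frame
#'   `lag_ms, prob`), `threshold`.
#' @export
opto_tag <- function(spikes, pulses, bin_ms = 0.2, window_ms = 8,
                     baseline_ms = 50, k = 3) {
  if (length(pulses) < 50) stop("need at least 50 pulses")
  spikes <- sort(spikes)
  edges <- seq(-baseline_ms, window_ms, by = bin_ms)
  lag_counts <- numeric(length(edges) - 1)
  for (p in pulses) {
    rel <- (spikes[spikes >= p - baseline_ms / 1000 &
                     spikes < p + window_ms / 1000] - p) * 1000
    if (length(rel))
      lag_counts <- lag_counts + bin_counts(rel, edges)
  }
  prob <- lag_counts / length(pulses)
  centers <- edges[-length(edges)] + bin_ms / 2
  base <- prob[centers < 0]
  resp <- prob[centers > 0]
  base_sd <- stats::sd(base)
  p_floor <- 1 / (2 * length(pulses))
  base_sd <- max(base_sd, sqrt(p_floor * (1 - p_floor) / length(pulses)),
                 na.rm = TRUE)
  thr <- mean(base) + k * base_sd
  hit <- which(resp > thr)
  list(
    tagged = length(hit) > 0,
    latency_ms = if (length(hit)) centers[centers > 0][hit[1]] else NA_real_,
    psth = data.frame(lag_ms = centers, prob = prob),
    threshold = thr
  )
}

#' Normalized inter-spike-interval histogram
#'
#' @param spikes spike times, seconds (>= 2 spikes).
#' @param bin_ms bin width, ms.
#' @param max_ms histogram range, ms.
#' @return data frame `isi_ms` (bin centers), `prob` (sums to 1 over
#'   intervals within range).
#' @export
isi_histogram <- function(spikes, bin_ms = 1, max_ms = 500) {
  spikes <- sort(spikes)
  if (length(spikes) < 2) stop("need at least two spikes")
  isi <- round(diff(spikes) * 1000, 9)  # snap float jitter off bin edges
  edges <- seq(0, max_ms, by = bin_ms)
  cnt <- bin_counts(isi, edges)
  total <- sum(cnt)
  if (total == 0) stop("no inter-spike intervals within range")
  data.frame(isi_ms = edges[-length(edges)] + bin_ms / 2, prob = cnt / total)
}
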