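#' Bin spike trains and z-score per neuron
#'
#' Counts spikes of every neuron in half-open time bins
#' `[k*bin_width, (k+1)*bin_width)` over `interval` and standardizes each
#' neuron's count vector to zero mean and unit variance (population SD), so
#' that high-rate neurons do not dominate the subsequent eigendecomposition.
#' Neurons with zero count variance carry no co-activation information and
#' are excluded, with the mapping recorded.
#'
#' @param spikes spike trains (named list of spike-time vectors, or a data
#'   frame with columns `neuron_id`, `time`).
#' @param interval `c(start, end)` in seconds; bins are anchored at `start`.
#' @param bin_width bin width in seconds (default 0.025).
#' @return object of class `binned_activity`: `Z` (retained neurons x bins,
#'   each row mean 0 / SD 1), `bin_width`, `times` (bin centers), `included`
#'   and `excluded` neuron ids.
#' @export
bin_and_zscore <- function(spikes, interval, bin_width = 0.025) {
  trains <- as_spike_trains(spikes)
  stopifnot(length(interval) == 2, diff(interval) > 0, bin_width > 0)
  nb <- floor((interval[2] - interval[1]) / bin_width)
  if (nb < 2) stop("interval shorter than two bins")
  edges <- interval[1] + (0:nb) * bin_width
  counts <- t(vapply(trains, bin_counts, integer(nb), edges = edges))
  v <- apply(counts, 1, function(x) pop_sd(x))
  keep <- v > 0
  if (!any(keep)) stop("all neurons have zero count variance in this interval")
  Z <- t(apply(counts[keep, , drop = FALSE], 1, zscore_pop))
  rownames(Z) <- names(trains)[keep]
  structure(list(
    Z = Z, bin_width = bin_width,
    times = edges[-length(edges)] + bin_width / 2,
    included = names(trains)[keep],
    excluded = names(trains)[!keep]
  ), class = "binned_activity")
}

#' Number of significant co-activation patterns
#'
#' Counts the eigenvalues of the neuron correlation matrix that exceed the
#' Marcenko-Pastur upper bound `lambda_max = (1 + sqrt(N/B))^2` for
#' independent unit-variance data, where `N` is the number of retained
#' neurons and `B` the number of time bins. Eigenvalues above this bound
#' indicate co-activation structure that cannot be explained by chance.
#'
#' @param binned a [bin_and_zscore] result.
#' @return integer count of significant patterns.
#' @export
count_significant_patterns <- function(binned) {
  stopifnot(inherits(binned, "binned_activity"))
  Z <- binned$Z
  N <- nrow(Z); B <- ncol(Z)
  if (B <= N) stop("need more bins than neurons for the Marcenko-Pastur bound")
  C <- tcrossprod(Z) / B
  lambda_max <- (1 + sqrt(N / B))^2
  sum(eigen(C, symmetric = TRUE, only.values = TRUE)$values > lambda_max)
}

#' Extract assembly patterns by PCA + ICA
#'
#' Projects the z-scored activity matrix onto its top `n_patterns` principal
#' components and runs fastICA (deflation mode, seeded orthogonal start, up
#' to three restarts on non-convergence) in that subspace; each
#' independent component is back-projected to neuron space, unit-normalized,
#' and sign-fixed so its largest-magnitude entry is positive. Members are the
#' neurons whose weight exceeds the weight mean by more than two SD.
#'
#' @param binned a [bin_and_zscore] result.
#' @param n_patterns number of patterns (typically from
#'   [count_significant_patterns]).
#' @param seed integer seed for the ICA starting rotation.
#' @param maxit,tol fastICA iteration cap and convergence tolerance.
#' @param restarts additional seeded restarts on non-convergence.
#' @return list of `assembly_pattern` objects, each with unit-norm weight
#'   vector `w` (named by neuron id) and `members`.
#' @export
extract_patterns <- function(binned, n_patterns, seed = 1,
                             maxit = 500, tol = 1e-6, restarts = 3) {
  stopifnot(inherits(binned, "binned_activity"))
  Z <- binned$Z
  N <- nrow(Z)
  if (n_patterns < 1 || n_patterns > N)
    stop("n_patterns must lie in [1, retained neurons]")
  C <- tcrossprod(Z) / ncol(Z)
  eig <- eigen(C, symmetric = TRUE)
  V <- eig$vectors[, seq_len(n_patterns), drop = FALSE]
  Zproj <- crossprod(V, Z)                     # n_patterns x bins

  if (n_patterns == 1) {
    M <- matrix(1, 1, 1)
  } else {
    M <- NULL
    for (r in 0:restarts) {
      R0 <- random_rotation(n_patterns, substream_seed(seed, paste0("ica-", r)))
      fit <- tryCatch(
        ica::icafast(t(Zproj), nc = n_patterns, center = TRUE, alg = "def",
                     maxit = maxit, tol = tol, Rmat = R0),
        error = function(e) NULL
      )
      if (!is.null(fit) && all(fit$iter < maxit)) { M <- fit$M; break }
      if (!is.null(fit) && r == restarts) {
        warning("fastICA did not reach tol after ", restarts + 1,
                " seeded starts; using the final iterate")
        M <- fit$M
      }
    }
    if (is.null(M)) stop("fastICA failed to converge after restarts")
  }

  lapply(seq_len(n_patterns), function(k) {
    w <- as.numeric(V %*% M[, k])
    w <- w / sqrt(sum(w^2))
    if (w[which.max(abs(w))] < 0) w <- -w
    names(w) <- rownames(Z)
    new_assembly_pattern(w)
  })
}

new_assembly_pattern <- function(w) {
  stopifnot(abs(sqrt(sum(w^2)) - 1) < 1e-8, !is.null(names(w)))
  members <- names(w)[w > mean(w) + 2 * stats::sd(w)]
  structure(list(w = w, members = members), class = "assembly_pattern")
}

#' @export
print.assembly_pattern <- function(x, ...) {
  cat(sprintf("<assembly_pattern> %d neurons; members: %s\n",
              length(x$w), paste(x$members, collapse = ", ")))
  invisible(x)
}

# Zero-diagonal projector of a pattern (outer product of w with diag removed).
projector <- function(pattern) {
  P <- tcrossprod(pattern$w)
  diag(P) <- 0
  P
}

#' Track assembly activation strength in time
#'
#' Convolves each member-space spike train with a Gaussian kernel, samples it
#' on a uniform grid, z-scores it over the interval and evaluates the
#' quadratic form `A(t) = z(t)' P z(t)` where `P` is the pattern's outer
#' product with zeroed diagonal — so only genuine co-activations, never a
#' single neuron alone, contribute to the strength.
#'
#' @param pattern an `assembly_pattern`.
#' @param spikes spike trains covering the pattern's neurons.
#' @param interval `c(start, end)` seconds.
#' @param kernel_sd Gaussian kernel SD in seconds; the default
#'   `0.025/sqrt(12)` matches the variance of the 25-ms detection boxcar.
#' @param step evaluation grid step in seconds (default 1 ms).
#' @param r_thres activation threshold carried to [detect_activations].
#' @return `activation_trace`: `times`, `strength`, `step`, `r_thres`.
#' @export
activation_strength <- function(pattern, spikes, interval,
                                kernel_sd = 0.025 / sqrt(12), step = 0.001,
                                r_thres = 5) {
  stopifnot(inherits(pattern, "assembly_pattern"))
  trains <- as_spike_trains(spikes)
  miss <- setdiff(names(pattern$w), names(trains))
  if (length(miss)) stop("spike trains missing pattern neurons: ",
                         paste(miss, collapse = ", "))
  nb <- floor((interval[2] - interval[1]) / step)
  edges <- interval[1] + (0:nb) * step
  w <- pattern$w
  zs <- matrix(0, length(w), nb)
  alive <- logical(length(w))
  for (i in seq_along(w)) {
    x <- gauss_smooth(bin_counts(trains[[names(w)[i]]], edges), kernel_sd / step)
    if (pop_sd(x) > 0) {
      zs[i, ] <- zscore_pop(x)
      alive[i] <- TRUE
    }
  }
  if (!all(alive)) {
    message("dropping ", sum(!alive), " zero-variance neuron(s) from pattern; ",
            "weights renormalized")
    w <- w[alive]
    if (!length(w)) stop("no active pattern neurons in interval")
    w <- w / sqrt(sum(w^2))
    zs <- zs[alive, , drop = FALSE]
  }
  # z' P z with zero diagonal == (w'z)^2 - sum_i w_i^2 z_i^2
  proj <- as.numeric(crossprod(w, zs))
  a <- proj^2 - as.numeric(crossprod(w^2, zs^2))
  structure(list(times = edges[-length(edges)] + step / 2, strength = a,
                 step = step, r_thres = r_thres),
            class = "activation_trace")
}

#' Detect assembly activations as supra-threshold strength peaks
#'
#' Activations are local maxima of the strength trace exceeding `r_thres`
#' (default 5), with a minimum separation of one detection bin width.
#'
#' @param trace an `activation_trace` (uniform grid).
#' @param r_thres strength threshold.
#' @param min_separation minimum peak separation, seconds.
#' @return numeric vector of peak times (possibly empty).
#' @export
detect_activations <- function(trace, r_thres = trace$r_thres %||% 5,
                               min_separation = 0.025) {
  s <- trace$strength
  n <- length(s)
  if (n < 3) return(numeric())
  is_peak <- c(FALSE, s[2:(n - 1)] > s[1:(n - 2)] & s[2:(n - 1)] >= s[3:n],
               FALSE) & s > r_thres
  idx <- which(is_peak)
  if (!length(idx)) return(numeric())
  # greedy non-maximum suppression within min_separation
  ord <- idx[order(s[idx], decreasing = TRUE)]
  kept <- numeric()
  for (i in ord) {
    ti <- trace$times[i]
    if (!length(kept) || all(abs(kept - ti) >= min_separation))
      kept <- c(kept, ti)
  }
  sort(kept)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Spatial map of assembly activation rate
#'
#' Bins activation peak times by the animal's position and divides per-bin
#' counts by occupancy time; bins never visited are `NA`.
#'
#' @param peaks activation times (seconds).
#' @param position data frame `t, x, y` covering the peak times.
#' @param spatial_bin_cm spatial bin side, cm.
#' @return list `rate`, `counts`, `occupancy` (matrices, x by y),
#'   `xedges`, `yedges`.
#' @export
assembly_map <- function(peaks, position, spatial_bin_cm = 4) {
  stopifnot(nrow(position) > 1)
  dt <- stats::median(diff(position$t))
  xe <- seq(floor(min(position$x)), ceiling(max(position$x)) + spatial_bin_cm,
            by = spatial_bin_cm)
  ye <- seq(floor(min(position$y)), ceiling(max(position$y)) + spatial_bin_cm,
            by = spatial_bin_cm)
  ix <- findInterval(position$x, xe, rightmost.closed = TRUE)
  iy <- findInterval(position$y, ye, rightmost.closed = TRUE)
  occ <- matrix(0, length(xe) - 1, length(ye) - 1)
  for (k in seq_along(ix)) occ[ix[k], iy[k]] <- occ[ix[k], iy[k]] + dt
  cnt <- matrix(0L, length(xe) - 1, length(ye) - 1)
  if (length(peaks)) {
    pxx <- approx(position$t, position$x, xout = peaks, rule = 2)$y
    pyy <- approx(position$t, position$y, xout = peaks, rule = 2)$y
    jx <- findInterval(pxx, xe, rightmost.closed = TRUE)
    jy <- findInterval(pyy, ye, rightmost.closed = TRUE)
    for (k in seq_along(jx)) cnt[jx[k], jy[k]] <- cnt[jx[k], jy[k]] + 1L
  }
  rate <- cnt / occ
  rate[occ == 0] <- NA_real_
  list(rate = rate, counts = cnt, occupancy = occ, xedges = xe, yedges = ye)
}

#' Similarity of two assembly patterns
#'
#' Absolute value of the inner product of the unit weight vectors; 1 for
#' identical (or sign-flipped) patterns, 0 for orthogonal ones. Patterns from
#' different sessions are intersected on their common neurons and
#' renormalized (logged) before the product.
#'
#' @param a,b `assembly_pattern` objects.
#' @return similarity in `[0, 1]`.
#' @export
pattern_similarity <- function(a, b) {
  common <- intersect(names(a$w), names(b$w))
  if (!length(common)) stop("patterns share no neurons")
  wa <- a$w[common]; wb <- b$w[common]
  if (length(common) < length(a$w) || length(common) < length(b$w)) {
    message("patterns intersected to ", length(common),
            " common neurons and renormalized")
    wa <- wa / sqrt(sum(wa^2))
    wb <- wb / sqrt(sum(wb^2))
  }
  abs(sum(wa * wb))
}

#' Match assembly patterns across sessions
#'
#' Computes the full pairwise similarity matrix between two pattern sets and
#' the one-to-one assignment maximizing total similarity (Hungarian
#' algorithm).
#'
#' @param set_a,set_b lists of `assembly_pattern` objects sharing a neuron
#'   space.
#' @return list `similarity` (|A| x |B| matrix) and `matching` (data frame
#'   `a, b, similarity`, one row per matched pair).
#' @export
match_patterns <- function(set_a, set_b) {
  S <- outer(seq_along(set_a), seq_along(set_b),
             Vectorize(function(i, j) pattern_similarity(set_a[[i]], set_b[[j]])))
  S <- matrix(S, length(set_a), length(set_b))
  if (nrow(S) == 0 || ncol(S) == 0)
    return(list(similarity = S,
                matching = data.frame(a = integer(), b = integer(),
                                      similarity = numeric())))
  transposed <- nrow(S) > ncol(S)
  Sw <- if (transposed) t(S) else S
  sol <- clue::solve_LSAP(Sw, maximum = TRUE)
  a_idx <- seq_len(nrow(Sw)); b_idx <- as.integer(sol)
  if (transposed) { tmp <- a_idx; a_idx <- b_idx; b_idx <- tmp }
  list(similarity = S,
       matching = data.frame(a = a_idx, b = b_idx,
                             similarity = S[cbind(a_idx, b_idx)]))
}

# Seeded random orthogonal matrix (QR of a Gaussian matrix).
random_rotation <- function(n, seed) {
  withr::with_seed(seed, {
    qr.Q(qr(matrix(stats::rnorm(n * n), n, n)))
  })
}
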