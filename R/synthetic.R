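#' Configuration of a synthetic recording session
#'
#' Assembles and validates all parameters of a simulated dual-site recording:
#' hippocampal pyramidal cells (PYR) with theta-phase and place modulation and
#' embedded 25-ms co-activation assemblies; accumbens populations (MSN, FSI,
#' TAN) with class-typical rates; monosynaptic PYR-to-FSI coupling;
#' FSI-to-MSN feedforward inhibition; and optogenetic suppression epochs.
#'
#' @param duration session length, seconds.
#' @param n_pyr,n_msn,n_fsi,n_tan population sizes.
#' @param pyr_rate,msn_rate,fsi_rate,tan_rate mean firing rates (Hz); scalar
#'   or one value per neuron. Defaults follow class physiology: FSIs fast,
#'   MSNs sparse.
#' @param theta_freq nominal theta frequency, Hz (4-12 band).
#' @param theta_kappa von Mises concentration of theta-phase modulation, one
#'   named entry per class (0 = unmodulated).
#' @param place_depth PYR place-field modulation depth in `[0, 1)`; 0 disables
#'   place tuning.
#' @param place_field_sd place-field width (cm).
#' @param assemblies list of assemblies, each
#'   `list(members = <neuron ids>, rate = <events/s>, participation = <prob>)`.
#'   At each assembly event every member emits one extra spike, independently
#'   with the given probability, uniformly within one 25-ms event window.
#' @param event_window assembly event window, seconds (default 0.025).
#' @param couplings data frame `pre, post, latency_ms, efficacy`: after each
#'   presynaptic spike the postsynaptic neuron fires one extra spike at the
#'   given latency (plus `coupling_jitter_ms` of Gaussian jitter) with
#'   probability `efficacy`.
#' @param coupling_jitter_ms SD of synaptic latency jitter, ms.
#' @param ffi data frame `fsi, msn, strength, tau_ms`: each FSI spike
#'   transiently scales the target MSN rate by `exp(-strength)` at the spike,
#'   recovering exponentially with time constant `tau_ms`.
#' @param light_epochs list of epochs
#'   `list(start =, end =, factors = c(<id> = <factor>, ...))`; within
#'   `[start, end)` each named neuron's rate is multiplied by its factor
#'   (0 silences it completely).
#' @param preference dwell fraction in enclosure A for the position trace.
#' @param cycle_jitter relative jitter of theta-cycle lengths.
#' @param separation waveform-bank class separation in feature SD units.
#' @param seed master integer seed; every randomized component draws from an
#'   independent substream keyed on this seed, so adding neurons or assemblies
#'   never perturbs existing spike trains.
#' @return a validated `session_config` list.
#' @export
session_config <- function(duration,
                           n_pyr = 50, n_msn = 0, n_fsi = 0, n_tan = 0,
                           pyr_rate = 2, msn_rate = 1.5, fsi_rate = 10,
                           tan_rate = 5,
                           theta_freq = 8,
                           theta_kappa = c(pyr = 0.8, msn = 0.2, fsi = 0.6,
                                           tan = 0),
                           place_depth = 0.3, place_field_sd = 10,
                           assemblies = list(),
                           event_window = 0.025,
                           couplings = NULL, coupling_jitter_ms = 0.3,
                           ffi = NULL,
                           light_epochs = list(),
                           preference = 0.5,
                           cycle_jitter = 0.02,
                           separation = 5,
                           seed = 1) {
  stopifnot(duration > 0, theta_freq >= 4, theta_freq <= 12,
            place_depth >= 0, place_depth < 1,
            preference >= 0, preference <= 1)
  counts <- c(pyr = n_pyr, msn = n_msn, fsi = n_fsi, tan = n_tan)
  if (any(counts < 0)) stop("neuron counts must be nonnegative")
  ids <- unlist(lapply(names(counts), function(cl) {
    if (counts[[cl]] > 0) paste0(cl, seq_len(counts[[cl]])) else character()
  }))
  classes <- sub("[0-9]+$", "", ids)
  rates <- c(rep_len(pyr_rate, n_pyr), rep_len(msn_rate, n_msn),
             rep_len(fsi_rate, n_fsi), rep_len(tan_rate, n_tan))
  if (any(rates < 0)) stop("rates must be nonnegative")
  names(rates) <- ids

  for (a in assemblies) {
    stopifnot(is.list(a), all(c("members", "rate", "participation") %in% names(a)))
    if (!all(a$members %in% ids)) stop("assembly references unknown neuron ids")
    if (a$rate < 0) stop("assembly rates must be nonnegative")
    if (a$participation < 0 || a$participation > 1)
      stop("participation probability must lie in [0,1]")
  }
  if (!is.null(couplings)) {
    stopifnot(all(c("pre", "post", "latency_ms", "efficacy") %in% names(couplings)))
    if (!all(c(couplings$pre, couplings$post) %in% ids))
      stop("coupling references unknown neuron ids")
    if (any(couplings$latency_ms <= 0)) stop("synaptic latencies must be > 0")
    if (any(couplings$efficacy < 0 | couplings$efficacy > 1))
      stop("efficacies must lie in [0,1]")
  }
  if (!is.null(ffi)) {
    stopifnot(all(c("fsi", "msn", "strength") %in% names(ffi)))
    if (is.null(ffi$tau_ms)) ffi$tau_ms <- 10
    if (!all(c(ffi$fsi, ffi$msn) %in% ids)) stop("ffi references unknown neuron ids")
  }
  for (ep in light_epochs) {
    stopifnot(is.list(ep), all(c("start", "end", "factors") %in% names(ep)))
    if (ep$start < 0 || ep$end > duration || ep$start >= ep$end)
      stop("light epochs must be non-empty intervals within [0, duration)")
    if (!all(names(ep$factors) %in% ids))
      stop("light epoch references unknown neuron ids")
    if (any(ep$factors < 0)) stop("suppression factors must be nonnegative")
  }

  structure(list(
    duration = duration, ids = ids, classes = classes, rates = rates,
    counts = counts,
    theta_freq = theta_freq, theta_kappa = theta_kappa,
    place_depth = place_depth, place_field_sd = place_field_sd,
    assemblies = assemblies, event_window = event_window,
    couplings = couplings, coupling_jitter_ms = coupling_jitter_ms,
    ffi = ffi, light_epochs = light_epochs,
    preference = preference, cycle_jitter = cycle_jitter,
    separation = separation, seed = as.integer(seed)
  ), class = "session_config")
}

#' Generate a complete synthetic recording session
#'
#' Produces spike trains, theta cycles, a position trace, a mean-waveform bank
#' and the generating ground truth. PYR spikes are inhomogeneous Poisson with
#' theta-phase (von Mises) and place-field rate modulation, normalized so each
#' neuron's marginal rate equals its configured rate. Assembly events inject
#' member spikes within a 25-ms window; coupled FSIs fire at fixed latency
#' after presynaptic PYR spikes with the configured transmission probability;
#' feedforward inhibition transiently dips MSN rates after connected-FSI
#' spikes; light epochs scale rates multiplicatively. Fully reproducible from
#' the config seed.
#'
#' @param config a [session_config].
#' @param dt rate-grid resolution, seconds.
#' @return list with elements `spikes` (named list of spike-time vectors),
#'   `cycles` ([theta_cycles]), `position` (data frame `t, x, y`),
#'   `waveforms` (bank from [generate_waveforms]), and `truth`
#'   (assembly memberships and event times, true classes, coupling graph).
#' @export
generate_session <- function(config, dt = 0.002) {
  stopifnot(inherits(config, "session_config"))
  seed <- config$seed
  dur <- config$duration
  cycles <- make_theta_cycles(dur + 0.5, config$theta_freq,
                              config$cycle_jitter,
                              substream_seed(seed, "theta"))
  geom <- cpp_geometry()
  position <- generate_cpp_trajectory(dur, geom, config$preference,
                                      seed = substream_seed(seed, "position"))

  tgrid <- seq(0, dur - dt, by = dt)
  phase <- phase_at(cycles, tgrid)
  phase[is.na(phase)] <- 0
  # position interpolated onto the rate grid for place-field modulation
  px <- approx(position$t, position$x, xout = tgrid, rule = 2)$y
  py <- approx(position$t, position$y, xout = tgrid, rule = 2)$y

  ids <- config$ids
  classes <- config$classes
  trains <- vector("list", length(ids))
  names(trains) <- ids

  light_factor_grid <- function(id) {
    f <- rep(1, length(tgrid))
    for (ep in config$light_epochs) {
      if (id %in% names(ep$factors))
        f[tgrid >= ep$start & tgrid < ep$end] <- ep$factors[[id]]
    }
    f
  }
  thin_by_light <- function(id, times, rng_key) {
    if (!length(times) || !length(config$light_epochs)) return(times)
    keep <- rep(TRUE, length(times))
    any_ep <- FALSE
    for (e in seq_along(config$light_epochs)) {
      ep <- config$light_epochs[[e]]
      if (!id %in% names(ep$factors)) next
      any_ep <- TRUE
      inside <- times >= ep$start & times < ep$end
      if (any(inside)) {
        f <- ep$factors[[id]]
        keep[inside] <- withr::with_seed(
          substream_seed(seed, paste0(rng_key, "-", e, "-", id)),
          stats::runif(sum(inside)) < f
        )
      }
    }
    if (!any_ep) times else times[keep]
  }

  # place-field centers (PYRs only), one substream per neuron
  centers <- lapply(ids, function(id) {
    withr::with_seed(substream_seed(seed, paste0("field-", id)),
                     c(stats::runif(1, 3, 43), stats::runif(1, 3, 43)))
  })
  names(centers) <- ids

  base_rate_grid <- function(id) {
    cl <- sub("[0-9]+$", "", id)
    r0 <- config$rates[[id]]
    if (r0 <= 0) return(rep(0, length(tgrid)))
    kap <- config$theta_kappa[[cl]]
    pref <- withr::with_seed(substream_seed(seed, paste0("phasepref-", id)),
                             stats::runif(1, 0, 2 * pi))
    mod <- if (kap > 0) exp(kap * cos(phase - pref)) else rep(1, length(tgrid))
    if (cl == "pyr" && config$place_depth > 0) {
      cen <- centers[[id]]
      d2 <- (px - cen[1])^2 + (py - cen[2])^2
      pf <- (1 - config$place_depth) +
        config$place_depth * exp(-d2 / (2 * config$place_field_sd^2))
      mod <- mod * pf
    }
    r0 * mod / mean(mod)
  }

  draw_poisson_train <- function(id, lambda) {
    withr::with_seed(substream_seed(seed, paste0("base-", id)), {
      cnt <- stats::rpois(length(lambda), lambda * dt)
      idx <- which(cnt > 0)
      if (!length(idx)) return(numeric())
      sort(rep(tgrid[idx], cnt[idx]) + stats::runif(sum(cnt[idx])) * dt)
    })
  }

  # --- assemblies: event times + member extra spikes -----------------------
  event_times <- vector("list", length(config$assemblies))
  extra <- lapply(ids, function(i) numeric())
  names(extra) <- ids
  for (k in seq_along(config$assemblies)) {
    a <- config$assemblies[[k]]
    ev <- withr::with_seed(substream_seed(seed, paste0("assembly-", k)), {
      n_ev <- stats::rpois(1, a$rate * dur)
      ev <- sort(stats::runif(n_ev, 0, dur - config$event_window))
      for (m in a$members) {
        hit <- stats::runif(length(ev)) < a$participation
        if (any(hit))
          extra[[m]] <- c(extra[[m]],
                          ev[hit] + stats::runif(sum(hit)) * config$event_window)
      }
      ev
    })
    event_times[[k]] <- ev
  }

  # --- base trains, in dependency order: pyr/tan, fsi (needs pyr), msn -----
  for (id in ids[classes %in% c("pyr", "tan")]) {
    lam <- base_rate_grid(id) * light_factor_grid(id)
    trains[[id]] <- draw_poisson_train(id, lam)
  }
  for (id in ids[classes == "pyr"])
    trains[[id]] <- sort(c(trains[[id]],
                           thin_by_light(id, extra[[id]], "light-extra")))

  # monosynaptic coupling: postsynaptic spikes triggered by presyn trains
  coupled_spikes <- lapply(ids, function(i) numeric())
  names(coupled_spikes) <- ids
  if (!is.null(config$couplings)) {
    for (i in seq_len(nrow(config$couplings))) {
      cp <- config$couplings[i, ]
      pre_t <- trains[[cp$pre]]
      if (is.null(pre_t) || !length(pre_t)) next
      add <- withr::with_seed(substream_seed(seed, paste0("coupling-", i)), {
        hit <- stats::runif(length(pre_t)) < cp$efficacy
        pre_t[hit] + cp$latency_ms / 1000 +
          stats::rnorm(sum(hit), 0, config$coupling_jitter_ms / 1000)
      })
      coupled_spikes[[cp$post]] <- c(coupled_spikes[[cp$post]],
                                     add[add >= 0 & add < dur])
    }
  }

  for (id in ids[classes == "fsi"]) {
    lam <- base_rate_grid(id) * light_factor_grid(id)
    own <- draw_poisson_train(id, lam)
    cpl <- thin_by_light(id, coupled_spikes[[id]], "light-coupled")
    trains[[id]] <- sort(c(own, cpl))
  }

  # feedforward inhibition: exponential multiplicative dip of MSN rates
  ffi_factor <- function(id) {
    f <- rep(1, length(tgrid))
    if (is.null(config$ffi)) return(f)
    rows <- which(config$ffi$msn == id)
    for (r in rows) {
      fsi_t <- trains[[config$ffi$fsi[r]]]
      if (!length(fsi_t)) next
      tau <- config$ffi$tau_ms[r] / 1000
      drive <- numeric(length(tgrid))
      idx <- findInterval(fsi_t, tgrid)
      idx <- idx[idx >= 1]
      for (j in idx) drive[j] <- drive[j] + 1
      # causal exponential filter, recursive form
      a <- exp(-dt / tau)
      drive <- stats::filter(drive, a, method = "recursive")
      f <- f * exp(-config$ffi$strength[r] * as.numeric(drive))
    }
    f
  }
  for (id in ids[classes == "msn"]) {
    lam <- base_rate_grid(id) * ffi_factor(id) * light_factor_grid(id)
    own <- draw_poisson_train(id, lam)
    cpl <- thin_by_light(id, coupled_spikes[[id]], "light-coupled")
    trains[[id]] <- sort(c(own, cpl))
  }

  wf <- generate_waveforms(
    class_counts = config$counts[c("msn", "fsi", "tan")],
    separation = config$separation,
    seed = substream_seed(seed, "waveforms")
  )

  truth <- list(
    assembly_memberships = lapply(config$assemblies, function(a) a$members),
    event_times = event_times,
    true_classes = stats::setNames(classes, ids),
    coupling_graph = config$couplings,
    light_epochs = config$light_epochs
  )

  list(spikes = structure(trains, class = "spike_trains"),
       cycles = cycles, position = position,
       waveforms = wf, truth = truth, config = config)
}

#' Generate a synthetic mean-waveform bank
#'
#' Builds per-neuron mean extracellular waveforms from parametric biphasic
#' templates (negative trough flanked by two positive peaks with small
#' undershoots) whose feature centroids — first-peak duration, second-peak
#' duration, spike symmetry — are class-specific: FSI templates are narrowest,
#' TAN broadest. Between-neuron jitter is Gaussian in feature space; centroid
#' offsets are scaled so the minimum pairwise centroid distance equals
#' `separation` in feature-SD units (0 collapses all classes onto one
#' centroid).
#'
#' @param class_counts named or positional counts for (MSN, FSI, TAN).
#' @param separation class separation in feature SD units (>= 0).
#' @param seed integer seed.
#' @param fs waveform sampling rate, Hz.
#' @param window_ms time window around the trough, ms.
#' @return list with `waveforms` (neuron x sample matrix), `t_ms` (sample
#'   times, trough at 0), `labels` (true classes), `features` (generating
#'   feature triplets), `fs`.
#' @export
generate_waveforms <- function(class_counts = c(msn = 100, fsi = 100, tan = 100),
                               separation = 5, seed = 1,
                               fs = 40000, window_ms = c(-2, 3)) {
  stopifnot(separation >= 0)
  if (is.null(names(class_counts))) names(class_counts) <- c("fsi", "msn", "tan")
  cls <- c("msn", "fsi", "tan")
  counts <- stats::setNames(as.integer(class_counts[cls]), cls)
  counts[is.na(counts)] <- 0L

  # physical feature centroids (first-peak ms, second-peak ms, symmetry)
  base <- rbind(msn = c(0.35, 0.50, 0.52),
                fsi = c(0.18, 0.25, 0.42),
                tan = c(0.55, 0.80, 0.62))
  sig <- c(0.030, 0.050, 0.040)  # between-neuron jitter SD per feature
  # `separation` is the per-feature RMS standardized centroid offset of the
  # closest class pair: offsets are scaled so the closest pair sits at
  # separation * sqrt(n_features) in jitter-SD units.
  std <- sweep(base, 2, sig, "/")
  dmin <- min(dist(std))
  alpha <- if (dmin > 0) separation * sqrt(ncol(base)) / dmin else 0
  grand <- colMeans(base)
  cen <- sweep(sweep(base, 2, grand, "-") * alpha, 2, grand, "+")

  n <- sum(counts)
  labels <- rep(cls, counts)
  feats <- withr::with_seed(seed, {
    f <- matrix(0, n, 3, dimnames = list(NULL, c("first_peak_ms",
                                                 "second_peak_ms", "symmetry")))
    for (j in 1:3) f[, j] <- cen[labels, j] + stats::rnorm(n, 0, sig[j])
    f[, 1] <- pmax(f[, 1], 0.08)
    f[, 2] <- pmax(f[, 2], 0.10)
    f[, 3] <- pmin(pmax(f[, 3], 0.05), 0.95)
    f
  })
  t_ms <- seq(window_ms[1], window_ms[2], by = 1000 / fs)
  w <- t(vapply(seq_len(max(n, 1)),
                function(i) if (n == 0) numeric(length(t_ms)) else
                  biphasic_template(t_ms, feats[i, 1], feats[i, 2], feats[i, 3]),
                numeric(length(t_ms))))
  if (n == 0) w <- matrix(numeric(), 0, length(t_ms))
  list(waveforms = w, t_ms = t_ms, labels = labels, features = feats,
       jitter_sd = stats::setNames(sig, colnames(feats)), fs = fs)
}

# Biphasic spike template with analytically placed zero crossings: trough lobe
# of half-width c around t=0, left peak ending at -first_peak_ms, right peak
# ending at +second_peak_ms, small undershoots beyond each peak so the far
# zero crossings are genuine sign changes.
biphasic_template <- function(t_ms, first_peak_ms, second_peak_ms, symmetry,
                              peak_total = 0.8, undershoot = 0.05,
                              undershoot_ms = 0.25) {
  cl <- 0.35 * first_peak_ms
  cr <- 0.35 * second_peak_ms
  a1 <- symmetry * peak_total
  a2 <- (1 - symmetry) * peak_total
  w <- numeric(length(t_ms))
  # trough: asymmetric negative lobe with minimum exactly at t = 0
  i <- t_ms >= -cl & t_ms < 0
  w[i] <- -cos(0.5 * pi * t_ms[i] / cl)
  i <- t_ms >= 0 & t_ms <= cr
  w[i] <- -cos(0.5 * pi * t_ms[i] / cr)
  # flanking positive peaks
  i <- t_ms >= -first_peak_ms & t_ms < -cl
  w[i] <- a1 * sin(pi * (-t_ms[i] - cl) / (first_peak_ms - cl))
  i <- t_ms > cr & t_ms <= second_peak_ms
  w[i] <- a2 * sin(pi * (t_ms[i] - cr) / (second_peak_ms - cr))
  # undershoots beyond the peaks
  i <- t_ms >= -first_peak_ms - undershoot_ms & t_ms < -first_peak_ms
  w[i] <- -undershoot * a1 * sin(pi * (-t_ms[i] - first_peak_ms) / undershoot_ms)
  i <- t_ms > second_peak_ms & t_ms <= second_peak_ms + undershoot_ms
  w[i] <- -undershoot * a2 * sin(pi * (t_ms[i] - second_peak_ms) / undershoot_ms)
  w
}

#' Two-enclosure apparatus geometry
#'
#' Two 46 x 46 cm square enclosures joined by an 8-cm-long, 7-cm-wide bridge,
#' on a common cm coordinate frame (enclosure A on the left).
#'
#' @return list of rectangular masks `A`, `B`, `bridge`, each
#'   `c(xmin, xmax, ymin, ymax)`.
#' @export
cpp_geometry <- function() {
  list(A = c(0, 46, 0, 46),
       bridge = c(46, 54, 19.5, 26.5),
       B = c(54, 100, 0, 46))
}

#' Label position samples by apparatus region
#'
#' @param position data frame `t, x, y`.
#' @param geometry a [cpp_geometry] list of rectangular masks.
#' @return factor with levels `A`, `B`, `bridge`, `other`.
#' @export
label_positions <- function(position, geometry = cpp_geometry()) {
  lab <- rep("other", nrow(position))
  for (nm in names(geometry)) {
    r <- geometry[[nm]]
    inside <- position$x >= r[1] & position$x <= r[2] &
      position$y >= r[3] & position$y <= r[4]
    lab[inside & lab == "other"] <- nm
  }
  factor(lab, levels = c("A", "B", "bridge", "other"))
}

#' Generate a two-enclosure place-preference trajectory
#'
#' Smooth reflected random walk over two square enclosures and a connecting
#' bridge, sampled at 25 Hz. Enclosure visits follow a deterministic
#' alternating bout schedule sized so the dwell fraction in enclosure A among
#' enclosure samples equals `preference` (up to frame quantization); the
#' randomness lives in the within-enclosure path.
#'
#' @param duration seconds.
#' @param geometry [cpp_geometry] masks.
#' @param preference target dwell fraction in enclosure A, in `[0, 1]`.
#' @param seed integer seed.
#' @param fs frame rate, Hz.
#' @param bout_s length of one A+B visit cycle, seconds.
#' @return data frame `t, x, y` (cm).
#' @export
generate_cpp_trajectory <- function(duration, geometry = cpp_geometry(),
                                    preference = 0.5, seed = 1, fs = 25,
                                    bout_s = 60) {
  stopifnot(preference >= 0, preference <= 1, duration > 0)
  n <- floor(duration * fs)
  tt <- (seq_len(n) - 1) / fs
  traverse_s <- 0.6
  # deterministic schedule of enclosure occupancy per frame
  in_A <- logical(n)
  on_bridge <- logical(n)
  if (preference == 1) {
    in_A[] <- TRUE
  } else if (preference == 0) {
    in_A[] <- FALSE
  } else {
    cyc <- bout_s
    enc_per_cyc <- cyc - 2 * traverse_s
    tA <- preference * enc_per_cyc
    tB <- (1 - preference) * enc_per_cyc
    ph <- tt %% cyc
    in_A <- ph < tA
    on_bridge <- (ph >= tA & ph < tA + traverse_s) |
      (ph >= tA + traverse_s + tB)
  }

  rects <- geometry
  walk <- function(nsteps, rect, x0, y0, seed) {
    withr::with_seed(seed, {
      x <- numeric(nsteps); y <- numeric(nsteps)
      vx <- 0; vy <- 0
      cx <- x0; cy <- y0
      for (k in seq_len(nsteps)) {
        vx <- 0.85 * vx + stats::rnorm(1, 0, 0.18)
        vy <- 0.85 * vy + stats::rnorm(1, 0, 0.18)
        cx <- cx + vx; cy <- cy + vy
        if (cx < rect[1] + 1) { cx <- 2 * (rect[1] + 1) - cx; vx <- -vx }
        if (cx > rect[2] - 1) { cx <- 2 * (rect[2] - 1) - cx; vx <- -vx }
        if (cy < rect[3] + 1) { cy <- 2 * (rect[3] + 1) - cy; vy <- -vy }
        if (cy > rect[4] - 1) { cy <- 2 * (rect[4] - 1) - cy; vy <- -vy }
        x[k] <- cx; y[k] <- cy
      }
      cbind(x, y)
    })
  }

  x <- numeric(n); y <- numeric(n)
  # fill runs of constant region with reflected walks continuing from the
  # previous run's end point
  region <- ifelse(on_bridge, "bridge", ifelse(in_A, "A", "B"))
  runs <- rle(region)
  pos <- 1L
  curx <- NA_real_; cury <- NA_real_
  for (ri in seq_along(runs$lengths)) {
    len <- runs$lengths[ri]
    idx <- pos:(pos + len - 1L)
    reg <- runs$values[ri]
    if (reg == "bridge") {
      # straight traverse across the bridge, direction given by neighbors
      br <- rects$bridge
      going_right <- ri > 1 && runs$values[ri - 1] == "A"
      xs <- seq(br[1], br[2], length.out = len + 2)[2:(len + 1)]
      if (!going_right) xs <- rev(xs)
      x[idx] <- xs
      y[idx] <- mean(br[3:4])
    } else {
      r <- rects[[reg]]
      x0 <- if (is.na(curx)) mean(r[1:2]) else min(max(curx, r[1] + 1), r[2] - 1)
      y0 <- if (is.na(cury)) mean(r[3:4]) else min(max(cury, r[3] + 1), r[4] - 1)
      w <- walk(len, r, x0, y0, substream_seed(seed, paste0("walk-", ri)))
      x[idx] <- w[, 1]; y[idx] <- w[, 2]
    }
    curx <- x[idx[len]]; cury <- y[idx[len]]
    pos <- pos + len
  }
  data.frame(t = tt, x = x, y = y)
}
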