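#' Place-preference score
#'
#' `(t_target - t_other) / (t_target + t_other)` where the times are dwell
#' seconds in the two enclosures; time on the bridge (or outside both
#' enclosures) is excluded from the denominator. With the sucrose-paired
#' enclosure as target this is the conditioned place-preference (CPP) score;
#' with the novel enclosure as target, the novelty-preference (NPP) score.
#' Tracking gaps up to `max_gap_s` are linearly interpolated, longer gaps
#' dropped.
#'
#' @param position data frame `t, x, y` (cm, 25 Hz typical).
#' @param geometry apparatus masks from [cpp_geometry].
#' @param target which enclosure (`"A"` or `"B"`) was paired with the
#'   reinforcer.
#' @param max_gap_s longest tracking gap to interpolate, seconds.
#' @return list `score`, `t_target`, `t_other`, `t_excluded` (seconds).
#' @export
preference_score <- function(position, geometry = cpp_geometry(),
                             target = c("A", "B"), max_gap_s = 0.5) {
  target <- match.arg(target)
  position <- fill_position_gaps(position, max_gap_s)
  dt <- stats::median(diff(position$t))
  lab <- label_positions(position, geometry)
  tA <- sum(lab == "A") * dt
  tB <- sum(lab == "B") * dt
  t_exc <- sum(lab %in% c("bridge", "other")) * dt
  t_target <- if (target == "A") tA else tB
  t_other <- if (target == "A") tB else tA
  if (t_target + t_other == 0) stop("no dwell time in either enclosure")
  list(score = (t_target - t_other) / (t_target + t_other),
       t_target = t_target, t_other = t_other, t_excluded = t_exc)
}

# Linear interpolation of NA tracking samples across gaps up to max_gap_s;
# longer gaps stay NA and are dropped.
fill_position_gaps <- function(position, max_gap_s = 0.5) {
  bad <- !is.finite(position$x) | !is.finite(position$y)
  if (!any(bad)) return(position)
  runs <- rle(bad)
  dt <- stats::median(diff(position$t))
  pos <- 1L
  for (ri in seq_along(runs$lengths)) {
    len <- runs$lengths[ri]
    if (runs$values[ri] && len * dt <= max_gap_s) {
      idx <- pos:(pos + len - 1L)
      good <- which(!bad)
      position$x[idx] <- approx(position$t[good], position$x[good],
                                xout = position$t[idx], rule = 2)$y
      position$y[idx] <- approx(position$t[good], position$y[good],
                                xout = position$t[idx], rule = 2)$y
    }
    pos <- pos + len
  }
  position[is.finite(position$x) & is.finite(position$y), , drop = FALSE]
}

#' Spatial occupancy map
#'
#' Dwell seconds per spatial bin; the map total equals the trace duration up
#' to one frame interval.
#'
#' @param position data frame `t, x, y`.
#' @param spatial_bin_cm bin side, cm.
#' @return list `occupancy` (x by y matrix, seconds), `xedges`, `yedges`.
#' @export
occupancy_map <- function(position, spatial_bin_cm = 4) {
  stopifnot(nrow(position) >= 1)
  dt <- if (nrow(position) > 1) stats::median(diff(position$t)) else 1
  xe <- seq(floor(min(position$x)),
            ceiling(max(position$x)) + spatial_bin_cm, by = spatial_bin_cm)
  ye <- seq(floor(min(position$y)),
            ceiling(max(position$y)) + spatial_bin_cm, by = spatial_bin_cm)
  ix <- findInterval(position$x, xe, rightmost.closed = TRUE)
  iy <- findInterval(position$y, ye, rightmost.closed = TRUE)
  occ <- matrix(0, length(xe) - 1, length(ye) - 1)
  for (k in seq_along(ix)) occ[ix[k], iy[k]] <- occ[ix[k], iy[k]] + dt
  list(occupancy = occ, xedges = xe, yedges = ye)
}

#' Count events per apparatus region
#'
#' Assigns each event (for example a nose poke) to an apparatus region by
#' its position, or uses supplied region labels directly.
#'
#' @param events data frame with either `x, y` columns (cm) or a `region`
#'   column with labels in `A, B, bridge, other`.
#' @param geometry apparatus masks from [cpp_geometry].
#' @return named integer vector of counts over `A, B, bridge, other`.
#' @export
count_events_by_region <- function(events, geometry = cpp_geometry()) {
  lv <- c("A", "B", "bridge", "other")
  if (nrow(events) == 0)
    return(stats::setNames(integer(4), lv))
  lab <- if ("region" %in% names(events)) {
    factor(as.character(events$region), levels = lv)
  } else {
    label_positions(events, geometry)
  }
  cnt <- as.integer(table(lab)[lv])
  stats::setNames(cnt, lv)
}
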