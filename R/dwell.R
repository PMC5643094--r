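#' Select cortex-contacting tracks and compute dwell events
#'
#' Implements the cortical dwell-time procedure: a track qualifies when it
#' comes within \code{contact_dist} of the cortex and approaches it at an
#' angle of at least \code{min_angle} degrees to the local cortex tangent.
#' Contact time is the first sampled frame within \code{contact_dist} of
#' the boundary after the track has first been at least that far from it
#' (comets nucleate on the cortex, so the initial cortical frames do not
#' count as contact); no sub-frame interpolation is applied.  The dwell
#' time is the interval from contact to the track's disappearance (its
#' last frame).  Only the first qualifying contact of each track is used.
#'
#' The approach angle is the angle (0-90 degrees) between the track's mean
#' heading over its last \code{k} pre-contact steps and the cortex tangent
#' at the boundary point nearest the contact position; tracks grazing the
#' cortex at shallow angles (< \code{min_angle}) are excluded, as are
#' tracks whose contact falls on their first frame (no pre-contact
#' heading).
#'
#' @param tracks a track table.
#' @param geom an \code{oocyte_geometry}.
#' @param contact_dist contact distance in um (default 1).
#' @param min_angle minimum approach angle in degrees (default 20).
#' @param k number of pre-contact steps over which the approach heading is
#'   averaged (default 3).
#' @return data.frame of dwell events: \code{track_id, contact_time,
#'   end_time, dwell, cortex_region, approach_angle}.  Tracks that never
#'   qualify are absent.
#' @export
select_cortex_tracks <- function(tracks, geom, contact_dist = 1,
                                 min_angle = 20, k = 3L) {
  stopifnot(inherits(geom, "oocyte_geometry"))
  trs <- split_tracks(tracks)
  rows <- list()
  for (tr in trs) {
    if (nrow(tr) < 2L) next
    d <- distance_to_cortex(cbind(tr$x_um, tr$y_um), geom)
    armed <- d >= contact_dist
    first_far <- if (any(armed)) which(armed)[1] else NA_integer_
    if (is.na(first_far)) next
    hits <- which(d < contact_dist & seq_along(d) > first_far)
    if (!length(hits)) next
    ci <- hits[1]
    if (ci < 2L) next
    lo <- max(1L, ci - as.integer(k))
    hx <- tr$x_um[ci] - tr$x_um[lo]
    hy <- tr$y_um[ci] - tr$y_um[lo]
    if (hx == 0 && hy == 0) next  # stationary approach: no defined heading
    nb <- .nearest_boundary_point(c(tr$x_um[ci], tr$y_um[ci]), geom$cortex)
    tang <- nb$tangent
    cosang <- abs(hx * tang[1] + hy * tang[2]) / sqrt(hx^2 + hy^2)
    ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi  # in [0, 90]
    if (ang < min_angle) next
    reg <- geom$region_labels[nb$edge]
    rows[[length(rows) + 1L]] <- data.frame(
      track_id = tr$track_id[1],
      contact_time = tr$t_s[ci],
      end_time = tr$t_s[nrow(tr)],
      dwell = tr$t_s[nrow(tr)] - tr$t_s[ci],
      cortex_region = if (reg == "posterior") "posterior" else "lateral",
      approach_angle = ang,
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(track_id = character(), contact_time = numeric(),
                      end_time = numeric(), dwell = numeric(),
                      cortex_region = character(),
                      approach_angle = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Dwell time of an event
#'
#' @param event one row of a dwell-event table.
#' @return dwell in s (\code{end_time - contact_time}).
#' @export
dwell_time <- function(event) {
  event$end_time - event$contact_time
}

#' Maximum-likelihood location-scale t fit
#'
#' Fits a location-scale Student t distribution (location \code{mu}, scale
#' \code{sigma}, degrees of freedom \code{nu}) to a sample by maximising
#' the likelihood with \code{nu} bounded to [0.5, 100]; a fit that lands on
#' the \code{nu} bound is flagged (\code{at_bound}), which for the upper
#' bound indicates an effectively normal sample.
#'
#' @param x numeric sample, at least 10 values.
#' @param nu_bounds bounds for the degrees of freedom.
#' @return object of class \code{"tls_fit"} with \code{mu}, \code{sigma},
#'   \code{nu}, \code{loglik}, \code{n}, \code{at_bound},
#'   \code{convergence}, and the raw sample \code{mean}/\code{median}.
#' @examples
#' set.seed(1)
#' x <- 15 + 4 * stats::rt(500, df = 5)
#' fit_t_location_scale(x)
#' @export
fit_t_location_scale <- function(x, nu_bounds = c(0.5, 100)) {
  x <- as.numeric(x)
  if (length(x) < 10L)
    stop("fit_t_location_scale needs at least 10 samples")
  if (stats::sd(x) == 0) stop("degenerate (constant) sample")
  nll <- function(par) {
    mu <- par[1]; sigma <- exp(par[2]); nu <- exp(par[3])
    -sum(stats::dt((x - mu) / sigma, df = nu, log = TRUE) - log(sigma))
  }
  start <- c(stats::median(x), log(stats::mad(x)), log(5))
  opt <- stats::optim(start, nll, method = "L-BFGS-B",
                      lower = c(-Inf, -20, log(nu_bounds[1])),
                      upper = c(Inf, 20, log(nu_bounds[2])),
                      control = list(maxit = 500))
  if (opt$convergence != 0)
    warning("t location-scale fit did not converge (code ",
            opt$convergence, "): ", opt$message)
  nu <- exp(opt$par[3])
  at_bound <- nu <= nu_bounds[1] * (1 + 1e-6) ||
    nu >= nu_bounds[2] * (1 - 1e-6)
  structure(list(mu = opt$par[1], sigma = exp(opt$par[2]), nu = nu,
                 loglik = -opt$value, n = length(x),
                 at_bound = at_bound, convergence = opt$convergence,
                 mean = mean(x), median = stats::median(x)),
            class = "tls_fit")
}

#' @export
print.tls_fit <- function(x, ...) {
  cat("Location-scale t fit (MLE)\n")
  cat(sprintf("  mu = %.3f, sigma = %.3f, nu = %.2f%s\n",
              x$mu, x$sigma, x$nu, if (x$at_bound) "  [at bound]" else ""))
  cat(sprintf("  logLik = %.2f on n = %d  (raw mean %.3f, median %.3f)\n",
              x$loglik, x$n, x$mean, x$median))
  invisible(x)
}

#' @export
coef.tls_fit <- function(object, ...) {
  c(mu = object$mu, sigma = object$sigma, nu = object$nu)
}

#' @export
logLik.tls_fit <- function(object, ...) {
  structure(object$loglik, df = 3L, nobs = object$n, class = "logLik")
}

#' Compare cortical dwell times between regions
#'
#' Pools dwell events per region and reports group means and maxima, the
#' Wilcoxon rank-sum p-value for a difference, and a location-scale t fit
#' per region (skipped with a note when a region has fewer than 10 events).
#'
#' @param posterior_events,lateral_events dwell-event tables (or numeric
#'   dwell vectors), >= 3 events each.
#' @return list of class \code{"dwell_comparison"}: per-region \code{n},
#'   \code{mean}, \code{max}; \code{rank_sum_p}; \code{fit_posterior},
#'   \code{fit_lateral} (\code{tls_fit} or NULL).
#' @export
compare_regions <- function(posterior_events, lateral_events) {
  dp <- if (is.numeric(posterior_events)) posterior_events
        else posterior_events$dwell
  dl <- if (is.numeric(lateral_events)) lateral_events
        else lateral_events$dwell
  if (length(dp) < 3L || length(dl) < 3L)
    stop("compare_regions needs at least 3 events per region")
  rs <- suppressWarnings(stats::wilcox.test(dp, dl, exact = FALSE))
  fitp <- if (length(dp) >= 10L && stats::sd(dp) > 0)
    fit_t_location_scale(dp) else NULL
  fitl <- if (length(dl) >= 10L && stats::sd(dl) > 0)
    fit_t_location_scale(dl) else NULL
  structure(list(
    n = c(posterior = length(dp), lateral = length(dl)),
    mean = c(posterior = mean(dp), lateral = mean(dl)),
    max = c(posterior = max(dp), lateral = max(dl)),
    rank_sum_p = rs$p.value,
    fit_posterior = fitp, fit_lateral = fitl),
    class = "dwell_comparison")
}

#' @export
print.dwell_comparison <- function(x, ...) {
  cat("Cortical dwell-time comparison\n")
  cat(sprintf("  posterior: n = %d, mean = %.2f s, max = %.2f s\n",
              x$n["posterior"], x$mean["posterior"], x$max["posterior"]))
  cat(sprintf("  lateral  : n = %d, mean = %.2f s, max = %.2f s\n",
              x$n["lateral"], x$mean["lateral"], x$max["lateral"]))
  cat(sprintf("  Wilcoxon rank-sum p = %.3g\n", x$rank_sum_p))
  invisible(x)
}

#' Kymograph occupancy matrix along a cortex segment
#'
#' Projects comet positions that lie within \code{capture} um of a cortical
#' polyline onto its arc length and bins them per frame, producing the
#' position x time occupancy matrix whose vertical lines correspond to
#' static (cortex-paused) comets.  Visual QC only.
#'
#' @param tracks a track table.
#' @param cortex_segment (m x 2) matrix: polyline along the cortex, um.
#' @param duration total duration in s.
#' @param bin arc-length bin width in um (default 0.5).
#' @param frame_dt frame interval in s.
#' @param capture maximum distance from the polyline, um (default 1).
#' @return integer matrix (arc-length bins x frames) of comet counts.
#' @export
render_kymograph <- function(tracks, cortex_segment, duration, bin = 0.5,
                             frame_dt = 1.7, capture = 1) {
  seg <- as.matrix(cortex_segment)
  if (nrow(seg) < 2L) stop("cortex_segment needs at least 2 points")
  seglen <- sqrt(diff(seg[, 1])^2 + diff(seg[, 2])^2)
  cum <- c(0, cumsum(seglen))
  total <- cum[length(cum)]
  nbin <- max(1L, ceiling(total / bin))
  nframes <- max(1L, ceiling(duration / frame_dt))
  out <- matrix(0L, nrow = nbin, ncol = nframes)
  if (nrow(tracks) == 0L) return(out)
  .check_track_table(tracks)
  e <- cbind(seg[-nrow(seg), 1], seg[-nrow(seg), 2],
             seg[-1, 1], seg[-1, 2])
  for (r in seq_len(nrow(tracks))) {
    f <- tracks$frame[r] + 1L
    if (f < 1L || f > nframes) next
    px <- tracks$x_um[r]; py <- tracks$y_um[r]
    dists <- .point_segment_dist(px, py, e)
    i <- which.min(dists)
    if (dists[i] > capture) next
    dx <- e[i, 3] - e[i, 1]; dy <- e[i, 4] - e[i, 2]
    len2 <- max(dx^2 + dy^2, .Machine$double.eps)
    t <- min(max(((px - e[i, 1]) * dx + (py - e[i, 2]) * dy) / len2, 0), 1)
    s <- cum[i] + t * sqrt(len2)
    b <- min(nbin, floor(s / bin) + 1L)
    out[b, f] <- out[b, f] + 1L
  }
  out
}
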