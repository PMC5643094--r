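#' Parameters for synthetic EB1 comet tracks
#'
#' Describes the statistical structure of growing microtubule plus-end
#' (EB1 comet) tracks in the oocyte cross-section: comets nucleate on the
#' anterior/lateral cortex, advance along a near-straight heading with a
#' position-dependent growth speed, and disappear either by catastrophe
#' (a position-dependent hazard) or by out-of-plane censoring (a hazard
#' proportional to comet age).  Comets that reach the cortex pause there
#' and disappear with a region-dependent cortical hazard, which is what the
#' cortical dwell-time procedure measures.
#'
#' Growth speed and catastrophe hazard switch between their "far" and
#' "near" values around \code{d_switch} um from the posterior pole through
#' a logistic ramp of width 2 um.
#'
#' @param n_comets number of comets to generate.
#' @param frame_dt frame interval in s (default 1.7, the imaging rate).
#' @param v_far,v_near mean growth speeds (um/s) beyond / within
#'   \code{d_switch} of the posterior pole; defaults 0.23 and 0.18.
#' @param v_sd per-step speed noise SD (um/s).
#' @param d_switch distance from the pole (um) at which speed and hazard
#'   ramp between regimes; default 15.
#' @param hazard_far,hazard_near catastrophe hazards (1/s) in the two
#'   regimes; default far hazard 1/11.3 (mean free lifespan 11.3 s).
#' @param censor_slope age-proportional out-of-plane loss hazard slope
#'   (1/s^2): the censoring hazard at comet age t is censor_slope * t.
#' @param pause_hazard_posterior,pause_hazard_lateral cortical
#'   disappearance hazards (1/s) once a comet has reached the posterior /
#'   non-posterior cortex; defaults 1/15 and 1/8 (mean cortical dwell
#'   times of 15 s and 8 s).
#' @param heading_sd angular noise SD per frame, degrees (default 2).
#' @param contact_dist cortical contact distance, um: a comet that comes
#'   within this distance of the cortex (after first having grown beyond
#'   it, since comets nucleate on the cortex) switches to the paused
#'   cortical state.  Default 1, the dwell-time contact rule.
#' @param max_frames hard cap on track length, frames.
#' @return a list of class \code{"eb1_params"}.
#' @export
eb1_params <- function(n_comets = 500, frame_dt = 1.7,
                       v_far = 0.23, v_near = 0.18, v_sd = 0.03,
                       d_switch = 15,
                       hazard_far = 1 / 11.3, hazard_near = 1 / 11.3,
                       censor_slope = 0,
                       pause_hazard_posterior = 1 / 15,
                       pause_hazard_lateral = 1 / 8,
                       heading_sd = 2, contact_dist = 1,
                       max_frames = 200L) {
  p <- list(n_comets = as.integer(n_comets), frame_dt = frame_dt,
            v_far = v_far, v_near = v_near, v_sd = v_sd,
            d_switch = d_switch, hazard_far = hazard_far,
            hazard_near = hazard_near, censor_slope = censor_slope,
            pause_hazard_posterior = pause_hazard_posterior,
            pause_hazard_lateral = pause_hazard_lateral,
            heading_sd = heading_sd, contact_dist = contact_dist,
            max_frames = as.integer(max_frames))
  .validate_eb1_params(p)
  class(p) <- "eb1_params"
  p
}

.validate_eb1_params <- function(p) {
  if (p$n_comets < 1L) stop("n_comets must be >= 1")
  if (p$frame_dt <= 0) stop("frame_dt must be positive")
  if (p$v_far <= 0 || p$v_near <= 0) stop("growth speeds must be positive")
  if (p$v_sd < 0) stop("v_sd must be non-negative")
  if (p$hazard_far < 0 || p$hazard_near < 0 || p$censor_slope < 0 ||
      p$pause_hazard_posterior < 0 || p$pause_hazard_lateral < 0)
    stop("hazards must be non-negative")
  invisible(p)
}

#' Parameters for synthetic oskar mRNP tracks
#'
#' Describes oskar-MS2 particle tracks: a fraction \code{mobile_fraction}
#' of particles undergo a directed run (kinesin transport) while the rest
#' stay put.  A mobile particle's run direction points into the posterior
#' half-plane (toward the pole) with a probability that depends on the
#' particle's starting distance band from the pole; per-step speeds are
#' normal, truncated at zero.
#'
#' @param n_particles number of particles.
#' @param frame_dt frame interval in s (the mRNP imaging rate is a free
#'   parameter; default 1).
#' @param speed_mean,speed_sd per-step speed distribution, um/s
#'   (defaults 0.36 and 0.10).
#' @param bias_by_band probability that a mobile run is posterior-directed,
#'   one entry per 10 um distance band starting at the pole; bands past the
#'   last entry reuse it.  Default c(0.71, 0.66, 0.63).
#' @param band_width width of the bias bands, um (default 10).
#' @param mobile_fraction probability a particle moves at all
#'   (default 0.12).
#' @param run_length_mean mean run length, um (exponential; default 3).
#' @param seed unused here; generation takes an explicit seed argument.
#' @return a list of class \code{"oskar_params"}.
#' @export
oskar_params <- function(n_particles = 500, frame_dt = 1,
                         speed_mean = 0.36, speed_sd = 0.10,
                         bias_by_band = c(0.71, 0.66, 0.63),
                         band_width = 10,
                         mobile_fraction = 0.12,
                         run_length_mean = 3) {
  p <- list(n_particles = as.integer(n_particles), frame_dt = frame_dt,
            speed_mean = speed_mean, speed_sd = speed_sd,
            bias_by_band = bias_by_band, band_width = band_width,
            mobile_fraction = mobile_fraction,
            run_length_mean = run_length_mean)
  if (p$n_particles < 1L) stop("n_particles must be >= 1")
  if (p$frame_dt <= 0) stop("frame_dt must be positive")
  if (p$speed_mean <= 0) stop("speed_mean must be positive")
  if (p$speed_sd < 0) stop("speed_sd must be non-negative")
  if (any(p$bias_by_band < 0) || any(p$bias_by_band > 1))
    stop("bias_by_band entries must be probabilities")
  if (p$mobile_fraction < 0 || p$mobile_fraction > 1)
    stop("mobile_fraction must be a probability")
  if (p$run_length_mean <= 0) stop("run_length_mean must be positive")
  class(p) <- "oskar_params"
  p
}

#' Generate synthetic EB1 comet tracks
#'
#' Simulates \code{params$n_comets} plus-end trajectories in the given
#' geometry and returns them as a track table (one row per point, columns
#' \code{track_id, kind, frame, t_s, x_um, y_um}).
#'
#' Each comet starts at a point uniform (by arc length) on the
#' anterior/lateral cortex with an initial heading uniform over directions
#' pointing into the interior, keeps that heading up to small per-frame
#' angular noise, and advances by speed x \code{frame_dt} per frame.  The
#' speed and the catastrophe hazard depend on the current distance to the
#' posterior pole.  When the advancing tip would leave the polygon the
#' comet is clamped to the cortex and switches to the cortical pause state,
#' where it stays in place and disappears with the region's pause hazard.
#'
#' @param params an \code{\link{eb1_params}} object.
#' @param geom an \code{oocyte_geometry}.
#' @param seed integer RNG seed.
#' @return a \code{data.frame} track table (kind \code{"eb1"}).
#' @examples
#' geom <- ellipse_geometry()
#' tr <- generate_eb1_tracks(eb1_params(n_comets = 20), geom, seed = 1)
#' head(tr)
#' @export
generate_eb1_tracks <- function(params, geom, seed = 1L) {
  stopifnot(inherits(params, "eb1_params"), inherits(geom, "oocyte_geometry"))
  .validate_eb1_params(params)
  set.seed(as.integer(seed))
  dt <- params$frame_dt
  starts <- .sample_cortex_points(geom, params$n_comets)
  rows <- vector("list", params$n_comets)
  for (i in seq_len(params$n_comets)) {
    p0 <- starts$points[i, ]
    nrm <- starts$normals[i, ]
    # heading uniform over the inward half-plane
    base <- atan2(nrm[2], nrm[1])
    theta <- base + stats::runif(1, -pi / 2, pi / 2)
    xs <- p0[1]; ys <- p0[2]
    paused <- FALSE
    armed <- FALSE   # becomes TRUE once the tip has left the contact band
    pause_h <- 0
    for (f in seq_len(params$max_frames - 1L)) {
      t_age <- (f - 1L) * dt
      cur <- c(xs[f], ys[f])
      if (!paused) {
        d_pole <- distance_to_posterior_pole(cur, geom)
        w <- stats::plogis((d_pole - params$d_switch) / 1) # ramp width ~2 um
        v_mean <- params$v_near + (params$v_far - params$v_near) * w
        hazard <- params$hazard_near +
          (params$hazard_far - params$hazard_near) * w
        # catastrophe or censoring during this frame ends the track here
        total_h <- hazard + params$censor_slope * t_age
        if (stats::runif(1) < 1 - exp(-total_h * dt)) break
        theta <- theta + stats::rnorm(1, 0, params$heading_sd * pi / 180)
        v <- max(stats::rnorm(1, v_mean, params$v_sd), 0)
        step <- v * dt
        dir <- c(cos(theta), sin(theta))
        nxt <- cur + step * dir
        if (!inside_cortex(nxt, geom, tol = 0)) {
          # clamp to the boundary along the heading; a tip already on the
          # boundary pointing outward stays put (growth stalls there)
          s <- .ray_exit_distance(cur, dir, geom)
          nxt <- if (is.finite(s)) cur + min(s, step) * dir else cur
        }
        d_cortex <- distance_to_cortex(nxt, geom)
        if (!armed && d_cortex >= params$contact_dist) armed <- TRUE
        if (armed && d_cortex < params$contact_dist) {
          # cortical contact: growth pauses; disappearance now follows the
          # region's cortical hazard
          paused <- TRUE
          reg <- nearest_cortex_region(nxt, geom)
          pause_h <- if (reg == "posterior") params$pause_hazard_posterior
                     else params$pause_hazard_lateral
        }
        xs <- c(xs, nxt[1]); ys <- c(ys, nxt[2])
      } else {
        # zero hazard = the tip persists (until max_frames)
        if (pause_h > 0 && stats::runif(1) < 1 - exp(-pause_h * dt)) break
        xs <- c(xs, xs[f]); ys <- c(ys, ys[f])
      }
    }
    nf <- length(xs)
    rows[[i]] <- data.frame(track_id = sprintf("eb1_%05d", i),
                            kind = "eb1",
                            frame = seq_len(nf) - 1L,
                            t_s = (seq_len(nf) - 1L) * dt,
                            x_um = xs, y_um = ys,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate synthetic oskar mRNP tracks
#'
#' Simulates \code{params$n_particles} particle trajectories.  Particles
#' start uniformly in the oocyte interior.  With probability
#' \code{mobile_fraction} a particle performs a straight run whose
#' direction is posterior-directed (within 90 degrees of the direction to
#' the pole) with the band-dependent probability, and whose length is
#' exponential with mean \code{run_length_mean}; otherwise it stays at its
#' starting point for a short track.  Runs stop at the cortex.
#'
#' @param params an \code{\link{oskar_params}} object.
#' @param geom an \code{oocyte_geometry}.
#' @param seed integer RNG seed.
#' @return a \code{data.frame} track table (kind \code{"oskar"}).
#' @export
generate_oskar_tracks <- function(params, geom, seed = 1L) {
  stopifnot(inherits(params, "oskar_params"), inherits(geom, "oocyte_geometry"))
  set.seed(as.integer(seed))
  dt <- params$frame_dt
  n <- params$n_particles
  starts <- .sample_interior_points(geom, n)
  mobile <- stats::runif(n) < params$mobile_fraction
  rows <- vector("list", n)
  nb <- length(params$bias_by_band)
  for (i in seq_len(n)) {
    p0 <- starts[i, ]
    if (!mobile[i]) {
      nf <- 5L
      rows[[i]] <- data.frame(track_id = sprintf("osk_%05d", i),
                              kind = "oskar",
                              frame = 0:(nf - 1L),
                              t_s = (0:(nf - 1L)) * dt,
                              x_um = rep(p0[1], nf), y_um = rep(p0[2], nf),
                              stringsAsFactors = FALSE)
      next
    }
    d0 <- distance_to_posterior_pole(p0, geom)
    band <- min(distance_band(d0, params$band_width) + 1L, nb)
    bias <- params$bias_by_band[band]
    to_pole <- atan2(geom$posterior_pole[2] - p0[2],
                     geom$posterior_pole[1] - p0[1])
    # posterior-directed: heading within +/-90 deg of the pole direction
    if (stats::runif(1) < bias)
      theta <- to_pole + stats::runif(1, -pi / 2, pi / 2)
    else
      theta <- to_pole + pi + stats::runif(1, -pi / 2, pi / 2)
    run_len <- stats::rexp(1, 1 / params$run_length_mean)
    dir <- c(cos(theta), sin(theta))
    xs <- p0[1]; ys <- p0[2]
    travelled <- 0
    repeat {
      v <- stats::rnorm(1, params$speed_mean, params$speed_sd)
      while (v <= 0) v <- stats::rnorm(1, params$speed_mean, params$speed_sd)
      step <- v * dt
      cur <- c(xs[length(xs)], ys[length(ys)])
      nxt <- cur + step * dir
      # the run stops at the cortex: a step that would exit is not taken
      if (!inside_cortex(nxt, geom, tol = 0)) break
      xs <- c(xs, nxt[1]); ys <- c(ys, nxt[2])
      travelled <- travelled + step
      if (travelled >= run_len) break
    }
    if (length(xs) < 2L) { # degenerate start on the cortex: keep it static
      xs <- rep(xs[1], 2L); ys <- rep(ys[1], 2L)
    }
    nf <- length(xs)
    rows[[i]] <- data.frame(track_id = sprintf("osk_%05d", i),
                            kind = "oskar",
                            frame = seq_len(nf) - 1L,
                            t_s = (seq_len(nf) - 1L) * dt,
                            x_um = xs, y_um = ys,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
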