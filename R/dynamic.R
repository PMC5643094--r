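#' Configuration of the dynamic microtubule / dynactin feedback model
#'
#' Microtubules nucleate at rate \code{r_nuc} per um of anterior/lateral
#' cortex, grow at \code{v_g}, undergo catastrophe with hazard
#' \code{k_cat0 / (1 + alpha * c(x))} at the plus-end position, and then
#' shrink at \code{v_s} to zero.  A plus end that reaches the cortex pauses
#' there with catastrophe hazard \code{cortex_pause / (1 + alpha * c(x))}.
#' Dynactin walkers ride microtubules plus-end-ward at \code{v_walk},
#' depositing into a concentration field \code{c(x)} on a regular grid;
#' \code{c} diffuses and decays.  Since microtubule plus-end growth is
#' posteriorly biased, deposition concentrates posteriorly, the posterior
#' plus ends are protected, grow further posterior, carry the walkers
#' further posterior - the anti-catastrophe positive feedback loop.
#' Setting \code{alpha = 0} switches the feedback off (the "mutant"
#' control); \code{alpha_v} optionally slows growth where \code{c} is high
#' (\code{v_g / (1 + alpha_v * c)}), reproducing the posterior slow-down.
#'
#' @param r_nuc nucleation rate, 1/s per um of anterior/lateral cortex.
#' @param v_g,v_s growth and shrinkage speeds, um/s (defaults 0.23 and
#'   0.4).
#' @param k_cat0 baseline catastrophe hazard in the cytoplasm, 1/s.
#' @param alpha dynactin anti-catastrophe coupling (dimensionless, per
#'   concentration unit); 0 disables the feedback.
#' @param alpha_v dynactin growth-damping coupling (0 = position-independent
#'   growth speed).
#' @param cortex_pause baseline cortical catastrophe hazard, 1/s (default
#'   1/8, the unprotected lateral dwell scale).
#' @param n_walkers number of dynactin walkers.
#' @param v_walk walker (kinesin) speed, um/s.
#' @param D_walker diffusion coefficient of unbound walkers, um^2/s.
#' @param capture_radius distance within which a free walker binds the
#'   nearest microtubule, um.
#' @param deposit deposition rate into c per walker, concentration units/s.
#' @param k_decay decay rate of c, 1/s.
#' @param D_c diffusion coefficient of c, um^2/s.
#' @param grid grid cell size for c, um.
#' @param T_total simulated time, s.
#' @param dt time step, s.
#' @param record_dt interval at which plus-end positions are recorded into
#'   comet-equivalent tracks, s (default 1.7, the comet imaging rate).
#' @param track_break_p probability per recorded frame that a comet track
#'   is interrupted and restarted under a new id (detection turnover: real
#'   comet trackers lose and re-acquire comets, so track starts sample the
#'   whole growth path rather than only nucleation sites).  Growing and
#'   cortex-paused plus ends are both recorded (a paused plus end is a
#'   static comet); growth speeds are extracted from the moving steps, see
#'   \code{\link{growth_speed_by_region}}.
#' @return list of class \code{"dynamic_mt_config"}.
#' @export
dynamic_mt_config <- function(r_nuc = 0.1, v_g = 0.23, v_s = 0.4,
                              k_cat0 = 0.02, alpha = 1, alpha_v = 0.3,
                              cortex_pause = 1 / 8,
                              n_walkers = 100, v_walk = 0.47,
                              D_walker = 0.05, capture_radius = 0.5,
                              deposit = 0.3, k_decay = 0.005, D_c = 0.25,
                              grid = 1, T_total = 1200, dt = 0.85,
                              record_dt = 1.7, track_break_p = 0.08) {
  cfg <- list(r_nuc = r_nuc, v_g = v_g, v_s = v_s, k_cat0 = k_cat0,
              alpha = alpha, alpha_v = alpha_v, cortex_pause = cortex_pause,
              n_walkers = as.integer(n_walkers), v_walk = v_walk,
              D_walker = D_walker, capture_radius = capture_radius,
              deposit = deposit, k_decay = k_decay, D_c = D_c,
              grid = grid, T_total = T_total, dt = dt,
              record_dt = record_dt, track_break_p = track_break_p)
  if (track_break_p < 0 || track_break_p >= 1)
    stop("track_break_p must be in [0, 1)")
  if (any(c(r_nuc, k_cat0, alpha, alpha_v, cortex_pause, deposit,
            k_decay, D_c) < 0))
    stop("rates and couplings must be non-negative")
  if (v_g <= 0 || v_s <= 0) stop("v_g and v_s must be positive")
  if (dt <= 0 || T_total < dt) stop("need dt > 0 and T_total >= dt")
  if (v_g * dt > grid)
    stop("unstable dt: growth step exceeds one grid cell")
  if (D_c * dt / grid^2 > 0.25)
    stop("unstable dt for the concentration field diffusion")
  class(cfg) <- "dynamic_mt_config"
  cfg
}

#' Run the dynamic microtubule / dynactin feedback simulation
#'
#' @param config a \code{\link{dynamic_mt_config}}.
#' @param geom an \code{oocyte_geometry}.
#' @param seed integer RNG seed.
#' @return object of class \code{"mt_dynamic_sim"}: \code{tracks}
#'   (comet-equivalent plus-end track table, one track per growth episode,
#'   sampled every \code{record_dt}), \code{dwell_log} (data.frame of
#'   simulated cortical contacts: region, dwell duration in s),
#'   \code{catastrophe_lengths} (lengths at cytoplasmic catastrophe, um),
#'   \code{c_field} (final concentration grid), \code{posterior_c}
#'   (time series of mean c within 10 um of the posterior pole),
#'   \code{config}, \code{seed}.
#' @export
run_dynamic_feedback <- function(config, geom, seed = 1L) {
  stopifnot(inherits(config, "dynamic_mt_config"),
            inherits(geom, "oocyte_geometry"))
  set.seed(as.integer(seed))
  dt <- config$dt
  nsteps <- floor(config$T_total / dt)
  record_every <- max(1L, round(config$record_dt / dt))

  ## concentration grid
  v <- geom$cortex
  h <- config$grid
  xb <- seq(min(v[, 1]) - h, max(v[, 1]) + h, by = h)
  yb <- seq(min(v[, 2]) - h, max(v[, 2]) + h, by = h)
  nx <- length(xb) - 1L; ny <- length(yb) - 1L
  cf <- matrix(0, nx, ny)
  xc <- (xb[-1] + xb[-length(xb)]) / 2
  yc <- (yb[-1] + yb[-length(yb)]) / 2
  cell_of <- function(px, py) {
    i <- pmin(pmax(findInterval(px, xb, rightmost.closed = TRUE), 1L), nx)
    j <- pmin(pmax(findInterval(py, yb, rightmost.closed = TRUE), 1L), ny)
    cbind(i, j)
  }
  # cells within 10 um of the posterior pole (posterior readout region)
  centres <- cbind(rep(xc, times = ny), rep(yc, each = nx))
  post_cells <- matrix(distance_to_posterior_pole(centres, geom) <= 10,
                       nx, ny)

  ## microtubule state (grown dynamically)
  cap <- 256L
  ax <- ay <- dx <- dy <- len <- exitd <- numeric(cap)
  state <- integer(cap)  # 0 empty, 1 growing, 2 paused, 3 shrinking
  track_no <- integer(cap)
  n_mt <- 0L
  next_track <- 1L
  contact_t <- rep(NA_real_, cap)

  arcs <- .cortex_arcs(geom)
  al_len <- sum(arcs$length[arcs$region != "posterior"])
  nuc_rate <- config$r_nuc * al_len * dt

  ## walkers: spatially local agents that diffuse when free, bind the
  ## nearest microtubule within the capture radius, and ride to the tip
  w_pos <- .sample_interior_points(geom, config$n_walkers)
  w_mt <- rep(NA_integer_, config$n_walkers)
  w_s <- rep(0, config$n_walkers)
  w_sigma <- sqrt(2 * config$D_walker * dt)

  grow_slots <- function(need) {
    while (n_mt + need > cap) {
      extra <- cap
      ax <<- c(ax, numeric(extra)); ay <<- c(ay, numeric(extra))
      dx <<- c(dx, numeric(extra)); dy <<- c(dy, numeric(extra))
      len <<- c(len, numeric(extra)); exitd <<- c(exitd, numeric(extra))
      state <<- c(state, integer(extra))
      track_no <<- c(track_no, integer(extra))
      contact_t <<- c(contact_t, rep(NA_real_, extra))
      cap <<- cap + extra
    }
  }

  track_log <- list()
  dwell_rows <- list()
  cat_lengths <- numeric(0)
  post_c_series <- numeric(0)
  lap_w <- config$D_c * dt / h^2

  for (step in seq_len(nsteps)) {
    t_now <- step * dt
    ## nucleation
    n_new <- stats::rpois(1, nuc_rate)
    if (n_new > 0) {
      grow_slots(n_new)
      sp <- .sample_cortex_points(geom, n_new,
                                  regions = c("anterior", "lateral"))
      base <- atan2(sp$normals[, 2], sp$normals[, 1])
      th <- base + stats::runif(n_new, -pi / 2, pi / 2)
      slots <- which(state == 0L)[seq_len(n_new)]
      ax[slots] <- sp$points[, 1]; ay[slots] <- sp$points[, 2]
      dx[slots] <- cos(th); dy[slots] <- sin(th)
      len[slots] <- 0
      exitd[slots] <- vapply(seq_len(n_new), function(k)
        .ray_exit_distance(sp$points[k, ], c(cos(th[k]), sin(th[k])), geom),
        0)
      state[slots] <- 1L
      track_no[slots] <- 0L  # comet id assigned at first recorded frame
      contact_t[slots] <- NA_real_
      n_mt <- max(n_mt, max(slots))
    }

    live <- which(state > 0L)
    if (length(live)) {
      px <- ax[live] + len[live] * dx[live]
      py <- ay[live] + len[live] * dy[live]
      ij <- cell_of(px, py)
      cval <- cf[ij]
      prot <- 1 + config$alpha * cval

      g <- state[live] == 1L
      p <- state[live] == 2L
      s <- state[live] == 3L

      ## growth (dynactin slows growth where concentrated)
      if (any(g)) {
        vg <- config$v_g / (1 + config$alpha_v * cval[g])
        newlen <- len[live[g]] + vg * dt
        hit <- newlen >= exitd[live[g]]
        len[live[g]] <- pmin(newlen, exitd[live[g]])
        if (any(hit)) {
          hi <- live[g][hit]
          state[hi] <- 2L
          contact_t[hi] <- t_now
        }
        ## cytoplasmic catastrophe for those still growing
        gi <- live[g][!hit]
        if (length(gi)) {
          kc <- config$k_cat0 / prot[g][!hit]
          cat <- stats::runif(length(gi)) < 1 - exp(-kc * dt)
          if (any(cat)) {
            ci <- gi[cat]
            cat_lengths <- c(cat_lengths, len[ci])
            state[ci] <- 3L
          }
        }
      }
      ## paused at cortex: protected cortical catastrophe hazard
      if (any(p)) {
        pi_ <- live[p]
        kc <- config$cortex_pause / prot[p]
        cat <- stats::runif(length(pi_)) < 1 - exp(-kc * dt)
        if (any(cat)) {
          ci <- pi_[cat]
          reg <- nearest_cortex_region(cbind(ax[ci] + len[ci] * dx[ci],
                                             ay[ci] + len[ci] * dy[ci]),
                                       geom)
          dwell_rows[[length(dwell_rows) + 1L]] <- data.frame(
            region = ifelse(reg == "posterior", "posterior", "lateral"),
            dwell = t_now - contact_t[ci],
            stringsAsFactors = FALSE)
          state[ci] <- 3L
        }
      }
      ## shrinkage
      if (any(s)) {
        si <- live[s]
        len[si] <- len[si] - config$v_s * dt
        dead <- si[len[si] <= 0]
        if (length(dead)) {
          state[dead] <- 0L
          len[dead] <- 0
          # walkers on dead MTs rebind a random live MT at its minus end
          lost <- which(!is.na(w_mt) & w_mt %in% dead)
          w_mt[lost] <- NA_integer_
        }
      }
    }

    ## record comet-equivalent plus-end positions: growing tips plus
    ## cortex-paused tips (static cortical comets are visible in EB1
    ## imaging; they are the vertical lines of the kymographs)
    if (step %% record_every == 0L) {
      vis <- which(state == 1L | state == 2L)
      if (length(vis)) {
        fresh <- vis[track_no[vis] == 0L]
        if (length(fresh)) {
          track_no[fresh] <- next_track + seq_along(fresh) - 1L
          next_track <- next_track + length(fresh)
        }
        track_log[[length(track_log) + 1L]] <- cbind(
          track_no[vis], t_now,
          ax[vis] + len[vis] * dx[vis],
          ay[vis] + len[vis] * dy[vis])
        # detection turnover: some comets restart under a new id
        if (config$track_break_p > 0) {
          broken <- vis[stats::runif(length(vis)) < config$track_break_p]
          track_no[broken] <- 0L
        }
      }
      post_c_series <- c(post_c_series, mean(cf[post_cells]))
    }

    ## dynactin walkers
    # release walkers whose microtubule vanished or shrank below them;
    # they stay where they are (their last tip position)
    w_gone <- which(!is.na(w_mt) &
                      (state[w_mt] == 0L |
                         (state[w_mt] == 3L & w_s > len[w_mt])))
    if (length(w_gone)) w_mt[w_gone] <- NA_integer_
    # bound walkers ride toward the plus end and track it once there
    act <- which(!is.na(w_mt))
    if (length(act)) {
      w_s[act] <- pmin(w_s[act] + config$v_walk * dt, len[w_mt[act]])
      w_pos[act, 1] <- ax[w_mt[act]] + w_s[act] * dx[w_mt[act]]
      w_pos[act, 2] <- ay[w_mt[act]] + w_s[act] * dy[w_mt[act]]
    }
    # free walkers diffuse locally and bind the nearest microtubule
    fw <- which(is.na(w_mt))
    if (length(fw)) {
      prop <- w_pos[fw, , drop = FALSE] +
        matrix(stats::rnorm(2L * length(fw), 0, w_sigma), ncol = 2L)
      ok <- inside_cortex(prop, geom, tol = 0)
      w_pos[fw[ok], ] <- prop[ok, , drop = FALSE]
      livemt <- which(state == 1L | state == 2L)
      if (length(livemt)) {
        dd <- .points_segments_dist(w_pos[fw, , drop = FALSE],
                                    ax[livemt], ay[livemt],
                                    dx[livemt], dy[livemt], len[livemt])
        nearest <- max.col(-dd$dist, ties.method = "first")
        mind <- dd$dist[cbind(seq_along(fw), nearest)]
        hit <- which(mind <= config$capture_radius)
        if (length(hit)) {
          idx <- fw[hit]
          w_mt[idx] <- livemt[nearest[hit]]
          w_s[idx] <- dd$t[cbind(hit, nearest[hit])]
          w_pos[idx, 1] <- ax[w_mt[idx]] + w_s[idx] * dx[w_mt[idx]]
          w_pos[idx, 2] <- ay[w_mt[idx]] + w_s[idx] * dy[w_mt[idx]]
        }
      }
    }
    # deposition into the concentration field: dynactin accumulates where
    # plus ends deliver it - walkers sitting at cortex-paused tips (the
    # ratchet endpoint of plus-end-directed transport); the field then
    # spreads into the nearby cytoplasm by diffusion
    parked <- which(!is.na(w_mt) & state[w_mt] == 2L &
                      w_s >= len[w_mt] - 1e-9)
    if (length(parked)) {
      ij <- cell_of(w_pos[parked, 1], w_pos[parked, 2])
      dep <- config$deposit * dt
      for (r in seq_len(nrow(ij)))
        cf[ij[r, 1], ij[r, 2]] <- cf[ij[r, 1], ij[r, 2]] + dep
    }

    ## concentration field: explicit diffusion + decay
    if (config$D_c > 0) {
      up <- rbind(cf[-1, , drop = FALSE], cf[nx, , drop = FALSE])
      dn <- rbind(cf[1, , drop = FALSE], cf[-nx, , drop = FALSE])
      le <- cbind(cf[, -1, drop = FALSE], cf[, ny, drop = FALSE])
      ri <- cbind(cf[, 1, drop = FALSE], cf[, -ny, drop = FALSE])
      cf <- cf + lap_w * (up + dn + le + ri - 4 * cf)
    }
    if (config$k_decay > 0) cf <- cf * exp(-config$k_decay * dt)
  }

  tracks <- if (length(track_log)) {
    m <- do.call(rbind, track_log)
    df <- data.frame(track_id = sprintf("sim_%06d", m[, 1]), kind = "eb1",
                     t_s = m[, 2], x_um = m[, 3], y_um = m[, 4],
                     stringsAsFactors = FALSE)
    df <- df[order(df$track_id, df$t_s), ]
    df$frame <- stats::ave(df$t_s, df$track_id,
                           FUN = function(t) seq_along(t) - 1L)
    df$t_s <- df$frame * config$record_dt  # uniform re-timing per track
    df[, c("track_id", "kind", "frame", "t_s", "x_um", "y_um")]
  } else {
    data.frame(track_id = character(), kind = character(),
               frame = integer(), t_s = numeric(), x_um = numeric(),
               y_um = numeric(), stringsAsFactors = FALSE)
  }
  dwell_log <- if (length(dwell_rows)) do.call(rbind, dwell_rows)
               else data.frame(region = character(), dwell = numeric())
  rownames(dwell_log) <- NULL
  structure(list(tracks = tracks, dwell_log = dwell_log,
                 catastrophe_lengths = cat_lengths,
                 c_field = cf, c_grid = list(xc = xc, yc = yc),
                 posterior_c = post_c_series,
                 config = config, seed = as.integer(seed)),
            class = "mt_dynamic_sim")
}

#' @export
print.mt_dynamic_sim <- function(x, ...) {
  cat("Dynamic microtubule / dynactin feedback simulation\n")
  cat(sprintf("  alpha = %.2f, T = %.0f s, seed = %d\n",
              x$config$alpha, x$config$T_total, x$seed))
  cat(sprintf("  comet-equivalent tracks : %d\n",
              length(unique(x$tracks$track_id))))
  cat(sprintf("  cortical contacts       : %d (%d posterior)\n",
              nrow(x$dwell_log), sum(x$dwell_log$region == "posterior")))
  if (length(x$posterior_c))
    cat(sprintf("  final posterior [dynactin] : %.3f\n",
                x$posterior_c[length(x$posterior_c)]))
  invisible(x)
}

#' Paired wild-type / mutant feedback scenario
#'
#' Runs the dynamic model twice on the same seed: once with the supplied
#' (wild-type) configuration and once with the feedback abolished
#' (\code{alpha = 0} and \code{alpha_v = 0}, i.e. position-independent
#' catastrophe and growth - the dynactin loss-of-function situation).
#' The comet-equivalent tracks of both runs feed directly into the track
#' analytics, reproducing the wild-type-vs-mutant contrasts in region
#' speed, posterior comet frequency and posterior lifespan.
#'
#' @param config wild-type \code{\link{dynamic_mt_config}} (must have
#'   \code{alpha > 0}).
#' @param geom an \code{oocyte_geometry}.
#' @param seed shared integer RNG seed.
#' @return list with elements \code{wildtype} and \code{mutant}, each an
#'   \code{mt_dynamic_sim}.
#' @export
mutant_scenario <- function(config, geom, seed = 1L) {
  stopifnot(inherits(config, "dynamic_mt_config"))
  if (config$alpha <= 0)
    stop("the wild-type configuration must have alpha > 0")
  mcfg <- config
  mcfg$alpha <- 0
  mcfg$alpha_v <- 0
  list(wildtype = run_dynamic_feedback(config, geom, seed),
       mutant = run_dynamic_feedback(mcfg, geom, seed))
}
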