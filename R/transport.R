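#' Configuration of the static-rod cargo transport model
#'
#' In the static-rod model the microtubules are fixed rods anchored on the
#' anterior/lateral cortex with random inward directions and exponential
#' lengths of mean \code{epsilon * L_AP} (truncated where the rod would
#' leave the cell).  Cargo alternates free diffusion (with optional
#' prescribed cytoplasmic circulation) and plus-end-directed walking on the
#' nearest rod; cargo that reaches a plus end lying within
#' \code{anchor_dist} of the posterior cortex is anchored there.
#'
#' For transport simulations the posterior (ncMTOC-free) cortical domain
#' should be the broad posterior exclusion zone rather than a narrow polar
#' cap: \code{ellipse_geometry(posterior_halfangle = 45)} reproduces the
#' observed ~60/40 posterior orientation bias of the plus ends.
#'
#' @param epsilon mean microtubule target length as a fraction of the
#'   anterior-posterior length (0 < epsilon <= 1; 0.5 reproduces the tight
#'   posterior crescent, 0.35 the diffuse posterior cloud).
#' @param n_mts number of rods.
#' @param n_cargo number of cargo particles.
#' @param v_walk kinesin walking speed, um/s (default 0.47, the measured
#'   mRNP transport speed).
#' @param D_cyto cargo diffusion coefficient, um^2/s.
#' @param k_unbind stochastic detachment rate while walking, 1/s.
#' @param flow \code{"off"} or \code{"circulation"} (a prescribed two-vortex
#'   circulation).
#' @param u flow speed scale, um/s (used when flow is on).
#' @param T_total total simulated time, s (default 10800 = 3 h).
#' @param dt time step, s.
#' @param capture_radius distance within which free cargo binds a rod, um.
#' @param anchor_dist distance from the posterior cortex within which a
#'   plus end delivers (anchors) its cargo, um.
#' @param grid cell size of the output density grid, um.
#' @return list of class \code{"static_rod_config"}.
#' @export
static_rod_config <- function(epsilon = 0.5, n_mts = 80, n_cargo = 400,
                              v_walk = 0.47, D_cyto = 0.05,
                              k_unbind = 0.05,
                              flow = c("off", "circulation"), u = 0.05,
                              T_total = 10800, dt = 1,
                              capture_radius = 0.5, anchor_dist = 1,
                              grid = 1) {
  flow <- match.arg(flow)
  cfg <- list(epsilon = epsilon, n_mts = as.integer(n_mts),
              n_cargo = as.integer(n_cargo), v_walk = v_walk,
              D_cyto = D_cyto, k_unbind = k_unbind, flow = flow, u = u,
              T_total = T_total, dt = dt, capture_radius = capture_radius,
              anchor_dist = anchor_dist, grid = grid)
  if (epsilon <= 0 || epsilon > 1) stop("epsilon must be in (0, 1]")
  if (dt <= 0 || T_total < dt) stop("need dt > 0 and T_total >= dt")
  if (v_walk < 0 || D_cyto < 0 || k_unbind < 0)
    stop("rates must be non-negative")
  if (v_walk * dt > capture_radius)
    stop("dt too large: walker step exceeds the capture radius")
  class(cfg) <- "static_rod_config"
  cfg
}

#' Sample static microtubule rods
#'
#' Anchors are uniform by arc length on the anterior + lateral cortex,
#' directions uniform over the inward half-plane at the anchor, and lengths
#' exponential with (pre-truncation) mean \code{epsilon * L_AP}, truncated
#' where the ray exits the cell.
#'
#' @param config a \code{\link{static_rod_config}}.
#' @param geom an \code{oocyte_geometry}.
#' @param seed integer RNG seed.
#' @return data.frame of rods: anchor \code{ax, ay}; unit direction
#'   \code{dx, dy}; \code{length} (um, after truncation);
#'   \code{raw_length} (pre-truncation exponential draw); plus-end
#'   coordinates \code{px, py}.
#' @export
sample_static_rods <- function(config, geom, seed = 1L) {
  stopifnot(inherits(config, "static_rod_config"),
            inherits(geom, "oocyte_geometry"))
  set.seed(as.integer(seed))
  n <- config$n_mts
  sp <- .sample_cortex_points(geom, n, regions = c("anterior", "lateral"))
  base <- atan2(sp$normals[, 2], sp$normals[, 1])
  theta <- base + stats::runif(n, -pi / 2, pi / 2)
  dx <- cos(theta); dy <- sin(theta)
  raw <- stats::rexp(n, rate = 1 / (config$epsilon * geom$L_AP))
  len <- raw
  for (i in seq_len(n)) {
    s <- .ray_exit_distance(sp$points[i, ], c(dx[i], dy[i]), geom)
    len[i] <- min(raw[i], s)
  }
  data.frame(ax = sp$points[, 1], ay = sp$points[, 2],
             dx = dx, dy = dy, length = len, raw_length = raw,
             px = sp$points[, 1] + len * dx,
             py = sp$points[, 2] + len * dy)
}

# prescribed two-vortex circulation, scaled to speed u; X is the AP
# coordinate and Y the orthogonal one, both normalised to [-1, 1]
.flow_velocity <- function(p, geom, u) {
  ap <- geom$ap_axis
  perp <- c(-ap[2], ap[1])
  proj <- cbind((p[, 1] - geom$centroid[1]) * ap[1] +
                (p[, 2] - geom$centroid[2]) * ap[2],
                (p[, 1] - geom$centroid[1]) * perp[1] +
                (p[, 2] - geom$centroid[2]) * perp[2])
  hx <- geom$L_AP / 2
  X <- proj[, 1] / hx
  Y <- proj[, 2] / hx
  # stream function psi = sin(pi (X+1)/2) sin(pi Y): one vortex per side
  vX <- u * sin(pi * (X + 1) / 2) * cos(pi * Y) * pi
  vY <- -u * cos(pi * (X + 1) / 2) * sin(pi * Y) * pi / 2
  cbind(vX * ap[1] + vY * perp[1], vX * ap[2] + vY * perp[2])
}

#' Run the static-rod cargo transport simulation
#'
#' Cargo particles are seeded uniformly in the cell.  Each time step a free
#' particle takes a diffusion step (plus prescribed flow advection when
#' enabled), rejected if it would leave the cell; a free particle within
#' the capture radius of a rod binds the nearest one (lowest rod index on
#' ties) at the nearest point; a bound particle walks toward the plus end
#' at \code{v_walk} and detaches at rate \code{k_unbind}.  A particle that
#' reaches a plus end lying within \code{anchor_dist} of the posterior
#' cortex becomes anchored (immobile); at any other plus end it detaches.
#'
#' @param rods a rod table from \code{\link{sample_static_rods}}.
#' @param config the \code{\link{static_rod_config}} used to sample them.
#' @param geom an \code{oocyte_geometry}.
#' @param seed integer RNG seed.
#' @return object of class \code{"mt_sim"}: \code{positions} (n_cargo x 2),
#'   \code{anchored} (logical), \code{density} (a \code{cargo_density}),
#'   \code{crescent} (the crescent score), \code{n_cargo}, \code{config},
#'   \code{seed}.
#' @export
run_cargo_transport <- function(rods, config, geom, seed = 1L) {
  stopifnot(inherits(config, "static_rod_config"),
            inherits(geom, "oocyte_geometry"))
  set.seed(as.integer(seed))
  dt <- config$dt
  n <- config$n_cargo
  pos <- .sample_interior_points(geom, n)
  state <- rep(0L, n)          # 0 free, 1 bound, 2 anchored
  rod_of <- rep(NA_integer_, n)
  s_along <- rep(NA_real_, n)
  nsteps <- floor(config$T_total / dt)
  sigma <- sqrt(2 * config$D_cyto * dt)
  # which plus ends deliver to the posterior cortex
  post_edges <- which(geom$region_labels == "posterior")
  e <- .edges(geom$cortex)[post_edges, , drop = FALSE]
  plus_post <- vapply(seq_len(nrow(rods)), function(i)
    min(.point_segment_dist(rods$px[i], rods$py[i], e)) <=
      config$anchor_dist, logical(1))
  S <- nrow(rods)
  for (step in seq_len(nsteps)) {
    ## bound cargo: walk toward the plus end
    b <- which(state == 1L)
    if (length(b)) {
      s_along[b] <- s_along[b] + config$v_walk * dt
      at_end <- b[s_along[b] >= rods$length[rod_of[b]]]
      if (length(at_end)) {
        s_along[at_end] <- rods$length[rod_of[at_end]]
        deliver <- at_end[plus_post[rod_of[at_end]]]
        release <- setdiff(at_end, deliver)
        state[deliver] <- 2L
        state[release] <- 0L
      }
      # stochastic unbinding
      still <- which(state == 1L)
      if (length(still) && config$k_unbind > 0) {
        off <- still[stats::runif(length(still)) <
                       1 - exp(-config$k_unbind * dt)]
        state[off] <- 0L
      }
      bb <- which(state == 1L | state == 2L)
      ri <- rod_of[bb]
      pos[bb, 1] <- rods$ax[ri] + s_along[bb] * rods$dx[ri]
      pos[bb, 2] <- rods$ay[ri] + s_along[bb] * rods$dy[ri]
      freed <- setdiff(b, which(state != 0L))
      rod_of[freed] <- NA_integer_
      s_along[freed] <- NA_real_
    }
    ## free cargo: diffusion (+ flow), reflecting (rejection) boundary
    f <- which(state == 0L)
    if (length(f)) {
      prop <- pos[f, , drop = FALSE] +
        matrix(stats::rnorm(2L * length(f), 0, sigma), ncol = 2L)
      if (config$flow == "circulation" && config$u != 0)
        prop <- prop + dt * .flow_velocity(pos[f, , drop = FALSE], geom,
                                           config$u)
      ok <- inside_cortex(prop, geom, tol = 0)
      pos[f[ok], ] <- prop[ok, , drop = FALSE]
      ## binding: nearest rod within the capture radius
      dmat <- .points_rods_dist(pos[f, , drop = FALSE], rods)
      nearest <- max.col(-dmat$dist, ties.method = "first")
      mind <- dmat$dist[cbind(seq_along(f), nearest)]
      hit <- which(mind <= config$capture_radius)
      if (length(hit)) {
        idx <- f[hit]
        state[idx] <- 1L
        rod_of[idx] <- nearest[hit]
        s_along[idx] <- dmat$t[cbind(hit, nearest[hit])]
        pos[idx, 1] <- rods$ax[rod_of[idx]] + s_along[idx] * rods$dx[rod_of[idx]]
        pos[idx, 2] <- rods$ay[rod_of[idx]] + s_along[idx] * rods$dy[rod_of[idx]]
      }
    }
  }
  dens <- cargo_density(pos, geom, cell = config$grid)
  structure(list(positions = pos, anchored = state == 2L,
                 state = state, density = dens,
                 crescent = crescent_score(dens, geom),
                 n_cargo = n, config = config, seed = as.integer(seed)),
            class = "mt_sim")
}

# distances (and arc-length foot points) from F points to S segments
# given as anchor + t * direction, t in [0, length]; returns F x S matrices
.points_segments_dist <- function(p, sax, say, sdx, sdy, slen) {
  Fn <- nrow(p); S <- length(sax)
  px <- matrix(p[, 1], Fn, S)
  py <- matrix(p[, 2], Fn, S)
  ax <- matrix(sax, Fn, S, byrow = TRUE)
  ay <- matrix(say, Fn, S, byrow = TRUE)
  dx <- matrix(sdx, Fn, S, byrow = TRUE)
  dy <- matrix(sdy, Fn, S, byrow = TRUE)
  ln <- matrix(slen, Fn, S, byrow = TRUE)
  t <- (px - ax) * dx + (py - ay) * dy
  t <- pmin(pmax(t, 0), ln)
  qx <- ax + t * dx
  qy <- ay + t * dy
  list(dist = sqrt((px - qx)^2 + (py - qy)^2), t = t)
}

.points_rods_dist <- function(p, rods) {
  .points_segments_dist(p, rods$ax, rods$ay, rods$dx, rods$dy, rods$length)
}

#' Cargo density on a regular grid
#'
#' @param pos (n x 2) cargo positions, um.
#' @param geom an \code{oocyte_geometry} (sets the grid extent).
#' @param cell cell size in um.
#' @return object of class \code{"cargo_density"}: \code{counts} matrix
#'   (x-cells x y-cells), cell-centre coordinates \code{xc}, \code{yc},
#'   \code{cell}, and \code{inside} (logical matrix: cell centre inside the
#'   cortex).
#' @export
cargo_density <- function(pos, geom, cell = 1) {
  v <- geom$cortex
  xr <- range(v[, 1]); yr <- range(v[, 2])
  xb <- seq(xr[1] - cell, xr[2] + cell, by = cell)
  yb <- seq(yr[1] - cell, yr[2] + cell, by = cell)
  xi <- findInterval(pos[, 1], xb, rightmost.closed = TRUE)
  yi <- findInterval(pos[, 2], yb, rightmost.closed = TRUE)
  nx <- length(xb) - 1L; ny <- length(yb) - 1L
  counts <- matrix(0L, nx, ny)
  ok <- xi >= 1L & xi <= nx & yi >= 1L & yi <= ny
  for (k in which(ok)) counts[xi[k], yi[k]] <- counts[xi[k], yi[k]] + 1L
  xc <- (xb[-1] + xb[-length(xb)]) / 2
  yc <- (yb[-1] + yb[-length(yb)]) / 2
  centres <- cbind(rep(xc, times = ny), rep(yc, each = nx))
  inside <- matrix(inside_cortex(centres, geom, tol = 0), nx, ny)
  structure(list(counts = counts, xc = xc, yc = yc, cell = cell,
                 inside = inside),
            class = "cargo_density")
}

#' Crescent score: cortical vs cytoplasmic posterior enrichment
#'
#' Ratio of the mean cargo density in a shell within \code{shell} um of the
#' posterior-labelled cortex arc to the mean density in the posterior third
#' of the cytoplasm excluding that shell.  Values > 1 indicate cortical
#' enrichment (a crescent); values near 1 a diffuse posterior cloud.
#' Returns \code{Inf} when all posterior cargo sits in the shell.
#'
#' @param density a \code{\link{cargo_density}}.
#' @param geom an \code{oocyte_geometry}.
#' @param shell shell thickness in um (default 2).
#' @return a single number (possibly \code{Inf}).
#' @export
crescent_score <- function(density, geom, shell = 2) {
  stopifnot(inherits(density, "cargo_density"),
            inherits(geom, "oocyte_geometry"))
  nx <- length(density$xc); ny <- length(density$yc)
  centres <- cbind(rep(density$xc, times = ny), rep(density$yc, each = nx))
  inside <- as.vector(density$inside)
  post_edges <- which(geom$region_labels == "posterior")
  if (!length(post_edges)) stop("geometry has no posterior-labelled arc")
  e <- .edges(geom$cortex)[post_edges, , drop = FALSE]
  dshell <- vapply(seq_len(nrow(centres)), function(i)
    min(.point_segment_dist(centres[i, 1], centres[i, 2], e)), 0)
  proj <- (centres[, 1] - geom$centroid[1]) * geom$ap_axis[1] +
          (centres[, 2] - geom$centroid[2]) * geom$ap_axis[2]
  vproj <- (geom$cortex[, 1] - geom$centroid[1]) * geom$ap_axis[1] +
           (geom$cortex[, 2] - geom$centroid[2]) * geom$ap_axis[2]
  third <- max(vproj) - geom$L_AP / 3
  in_shell <- inside & dshell <= shell
  in_region <- inside & !in_shell & proj >= third
  if (!any(in_shell) || !any(in_region))
    stop("empty shell or posterior region at this grid resolution")
  cnt <- as.vector(density$counts)
  ms <- mean(cnt[in_shell])
  mr <- mean(cnt[in_region])
  if (mr == 0) {
    if (ms == 0) return(NaN)
    return(Inf)
  }
  ms / mr
}

#' @export
print.mt_sim <- function(x, ...) {
  cat("Cargo transport simulation\n")
  cat(sprintf("  cargo     : %d (%d anchored at posterior cortex)\n",
              x$n_cargo, sum(x$anchored)))
  if (!is.null(x$crescent))
    cat(sprintf("  crescent  : %.3f\n", x$crescent))
  if (!is.null(x$config$epsilon))
    cat(sprintf("  epsilon   : %.2f\n", x$config$epsilon))
  invisible(x)
}
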