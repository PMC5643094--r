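# Independent brute-force oracles used across the test files.  These stay
# deliberately naive (plain loops, no shared helpers with the package
# internals) so they can arbitrate the fast implementations.

std_geom <- function() ellipse_geometry()

# direct min-over-edges segment scan (independent of .point_segment_dist)
brute_dist_to_polygon <- function(p, vertices) {
  n <- nrow(vertices)
  best <- Inf
  for (i in seq_len(n)) {
    a <- vertices[i, ]
    b <- vertices[if (i == n) 1L else i + 1L, ]
    ab <- b - a
    t <- sum((p - a) * ab) / sum(ab * ab)
    t <- min(max(t, 0), 1)
    q <- a + t * ab
    best <- min(best, sqrt(sum((p - q)^2)))
  }
  best
}

# step-by-step speed loop
brute_speed <- function(track) {
  s <- 0
  for (i in 2:nrow(track)) {
    d <- sqrt((track$x_um[i] - track$x_um[i - 1])^2 +
              (track$y_um[i] - track$y_um[i - 1])^2)
    s <- s + d / (track$t_s[i] - track$t_s[i - 1])
  }
  s / (nrow(track) - 1)
}

# brute-force dwell pipeline: per-frame distance scan + explicit angle
brute_dwell_events <- function(tracks, geom, contact_dist = 1,
                               min_angle = 20, k = 3) {
  out <- list()
  for (id in unique(tracks$track_id)) {
    tr <- tracks[tracks$track_id == id, ]
    tr <- tr[order(tr$t_s), ]
    if (nrow(tr) < 2) next
    d <- numeric(nrow(tr))
    for (i in seq_len(nrow(tr)))
      d[i] <- brute_dist_to_polygon(c(tr$x_um[i], tr$y_um[i]), geom$cortex)
    ci <- NA
    armed_at <- NA
    for (i in seq_len(nrow(tr))) {
      if (is.na(armed_at) && d[i] >= contact_dist) armed_at <- i
      if (!is.na(armed_at) && i > armed_at && d[i] < contact_dist) {
        ci <- i; break
      }
    }
    if (is.na(ci) || ci < 2) next
    lo <- max(1, ci - k)
    h <- c(tr$x_um[ci] - tr$x_um[lo], tr$y_um[ci] - tr$y_um[lo])
    if (all(h == 0)) next
    # nearest boundary point and tangent, by explicit scan
    best <- Inf; tang <- c(NA, NA); edge <- NA
    n <- nrow(geom$cortex)
    for (i in seq_len(n)) {
      a <- geom$cortex[i, ]
      b <- geom$cortex[if (i == n) 1L else i + 1L, ]
      ab <- b - a
      t <- sum((c(tr$x_um[ci], tr$y_um[ci]) - a) * ab) / sum(ab * ab)
      t <- min(max(t, 0), 1)
      q <- a + t * ab
      dd <- sqrt(sum((c(tr$x_um[ci], tr$y_um[ci]) - q)^2))
      if (dd < best) {
        best <- dd
        tang <- ab / sqrt(sum(ab * ab))
        edge <- i
      }
    }
    cosang <- abs(sum(h * tang)) / sqrt(sum(h * h))
    ang <- acos(min(max(cosang, -1), 1)) * 180 / pi
    if (ang < min_angle) next
    reg <- geom$region_labels[edge]
    out[[length(out) + 1]] <- data.frame(
      track_id = id,
      contact_time = tr$t_s[ci],
      end_time = tr$t_s[nrow(tr)],
      dwell = tr$t_s[nrow(tr)] - tr$t_s[ci],
      cortex_region = if (reg == "posterior") "posterior" else "lateral",
      approach_angle = ang,
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(track_id = character(), contact_time = numeric(),
                      end_time = numeric(), dwell = numeric(),
                      cortex_region = character(),
                      approach_angle = numeric()))
  do.call(rbind, out)
}

# a straight synthetic track from p0 with heading (deg) and speed (um/s)
straight_track <- function(p0, heading_deg, speed, n_frames, dt = 1,
                           id = "t1", kind = "eb1") {
  th <- heading_deg * pi / 180
  i <- seq_len(n_frames) - 1
  data.frame(track_id = id, kind = kind, frame = i, t_s = i * dt,
             x_um = p0[1] + i * speed * dt * cos(th),
             y_um = p0[2] + i * speed * dt * sin(th),
             stringsAsFactors = FALSE)
}

# minimal track-stats table for analytics that only need angles/distances
fake_stats <- function(net_angle, start_distance,
                       speed = 0.3, net_displacement = 2) {
  n <- length(net_angle)
  data.frame(track_id = sprintf("f%04d", seq_len(n)), kind = "oskar",
             n_frames = 5L, speed = speed, net_angle = net_angle,
             start_distance = start_distance, lifespan = 4,
             net_displacement = net_displacement,
             is_mobile = net_displacement >= 1,
             stringsAsFactors = FALSE)
}
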