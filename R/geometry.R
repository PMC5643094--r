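#' Oocyte cross-section geometry
#'
#' Builds and validates the 2D geometry of a stage 9 oocyte cross-section:
#' the cortex (a closed simple polygon), the posterior pole, the
#' anterior-posterior (AP) axis and per-vertex cortical region labels.
#' All distances and region queries used by the track analytics and the
#' transport simulators go through this object.
#'
#' Coordinates are in micrometres.  The polygon is given as an ordered set
#' of vertices; the closing edge from the last vertex back to the first is
#' implicit.  Each vertex carries a region label (\code{"anterior"},
#' \code{"lateral"} or \code{"posterior"}); an edge inherits the label of
#' its first vertex.
#'
#' @param cortex numeric matrix (n x 2) or data.frame of ordered vertex
#'   coordinates in um; at least 8 vertices.
#' @param posterior_pole length-2 numeric, a point lying on the cortex
#'   (within 1e-6 um of the polygon boundary).
#' @param ap_axis length-2 numeric, direction from anterior to posterior;
#'   normalised internally (must be nonzero).
#' @param region_labels character vector, one label per vertex, each one of
#'   \code{"anterior"}, \code{"lateral"}, \code{"posterior"}.
#' @return an object of class \code{"oocyte_geometry"}: a list with
#'   elements \code{cortex}, \code{posterior_pole}, \code{ap_axis},
#'   \code{region_labels}, \code{L_AP} (extent of the polygon projected on
#'   the AP axis, um) and \code{centroid}.
#' @examples
#' geom <- ellipse_geometry()
#' geom$L_AP
#' @export
build_geometry <- function(cortex, posterior_pole, ap_axis, region_labels) {
  cortex <- as.matrix(cortex)
  storage.mode(cortex) <- "double"
  if (ncol(cortex) != 2L)
    stop("cortex must have two columns (x, y)")
  if (nrow(cortex) < 8L)
    stop("cortex polygon needs at least 8 vertices")
  if (!all(is.finite(cortex)))
    stop("cortex coordinates must be finite")
  # drop an explicit closing vertex if present
  n <- nrow(cortex)
  if (isTRUE(all(cortex[1L, ] == cortex[n, ]))) {
    cortex <- cortex[-n, , drop = FALSE]
    if (length(region_labels) == n) region_labels <- region_labels[-n]
  }
  posterior_pole <- as.numeric(posterior_pole)
  ap_axis <- as.numeric(ap_axis)
  if (length(posterior_pole) != 2L || !all(is.finite(posterior_pole)))
    stop("posterior_pole must be a finite (x, y) point")
  nrm <- sqrt(sum(ap_axis^2))
  if (length(ap_axis) != 2L || !is.finite(nrm) || nrm == 0)
    stop("ap_axis must be a nonzero (x, y) vector")
  ap_axis <- ap_axis / nrm
  region_labels <- as.character(region_labels)
  if (length(region_labels) != nrow(cortex))
    stop("region_labels must have one label per cortex vertex")
  ok <- region_labels %in% c("anterior", "lateral", "posterior")
  if (!all(ok))
    stop("region_labels must be 'anterior', 'lateral' or 'posterior'")
  if (.polygon_self_intersects(cortex))
    stop("cortex polygon is self-intersecting")

  geom <- structure(
    list(cortex = cortex,
         posterior_pole = posterior_pole,
         ap_axis = ap_axis,
         region_labels = region_labels,
         L_AP = NA_real_,
         centroid = colMeans(cortex)),
    class = "oocyte_geometry")

  if (distance_to_cortex(posterior_pole, geom) > 1e-6)
    stop("posterior_pole does not lie on the cortex polygon")
  # posterior-labelled arc must contain the pole: nearest edge is posterior
  idx <- .nearest_edge(posterior_pole, cortex)
  if (region_labels[idx] != "posterior")
    stop("posterior_pole does not lie on a posterior-labelled cortex arc")

  proj <- cortex %*% ap_axis
  geom$L_AP <- max(proj) - min(proj)
  if (geom$L_AP <= 0) stop("degenerate geometry: L_AP must be positive")
  geom
}

#' @export
print.oocyte_geometry <- function(x, ...) {
  cat("Oocyte cross-section geometry\n")
  cat(sprintf("  vertices : %d (%s)\n", nrow(x$cortex),
              paste(sprintf("%s %d", names(table(x$region_labels)),
                            as.integer(table(x$region_labels))),
                    collapse = ", ")))
  cat(sprintf("  L_AP     : %.2f um\n", x$L_AP))
  cat(sprintf("  pole     : (%.2f, %.2f) um\n",
              x$posterior_pole[1], x$posterior_pole[2]))
  invisible(x)
}

#' Default elliptical oocyte geometry
#'
#' A convenience constructor for an elliptical cross-section with the
#' posterior pole on the positive AP axis.  Vertices within
#' \code{posterior_halfangle} degrees of the pole (as seen from the
#' centroid) are labelled posterior, those within \code{anterior_halfangle}
#' of the opposite (anterior) direction are labelled anterior, and the rest
#' lateral.
#'
#' @param a,b semi-axes in um (AP and dorso-ventral); defaults 25 x 20
#'   (a 50 x 40 um cross-section).
#' @param n_vertices number of polygon vertices.
#' @param posterior_halfangle,anterior_halfangle half-angles in degrees for
#'   region labelling.
#' @return an \code{oocyte_geometry}.
#' @export
ellipse_geometry <- function(a = 25, b = 20, n_vertices = 64,
                             posterior_halfangle = 15,
                             anterior_halfangle = 60) {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  cortex <- cbind(a * cos(th), b * sin(th))
  deg <- (th * 180 / pi) %% 360
  ang_from_pole <- pmin(deg, 360 - deg)
  labels <- rep("lateral", n_vertices)
  labels[ang_from_pole <= posterior_halfangle] <- "posterior"
  labels[abs(deg - 180) <= anterior_halfangle] <- "anterior"
  build_geometry(cortex, posterior_pole = c(a, 0), ap_axis = c(1, 0),
                 region_labels = labels)
}

#' Distance from a point to the posterior pole
#'
#' Euclidean distance in the imaging plane, the quantity against which all
#' distance-binned statistics are computed (the pole is 0 um).
#'
#' @param p length-2 numeric point or an (n x 2) matrix of points, um.
#' @param geom an \code{oocyte_geometry}.
#' @return numeric distance(s) in um.
#' @export
distance_to_posterior_pole <- function(p, geom) {
  stopifnot(inherits(geom, "oocyte_geometry"))
  p <- .as_points(p)
  sqrt((p[, 1] - geom$posterior_pole[1])^2 +
       (p[, 2] - geom$posterior_pole[2])^2)
}

#' Minimum distance from a point to the cortex polygon
#'
#' Minimum Euclidean distance to any cortex edge, used for the 1 um
#' cortical contact rule of the dwell-time procedure.
#'
#' @inheritParams distance_to_posterior_pole
#' @return numeric distance(s) in um (0 on the boundary; interior and
#'   exterior points both return positive values).
#' @export
distance_to_cortex <- function(p, geom) {
  stopifnot(inherits(geom, "oocyte_geometry"))
  p <- .as_points(p)
  e <- .edges(geom$cortex)
  out <- numeric(nrow(p))
  for (i in seq_len(nrow(p)))
    out[i] <- min(.point_segment_dist(p[i, 1], p[i, 2], e))
  out
}

#' Distance band index
#'
#' Assigns a distance from the posterior pole to a half-open band
#' \eqn{[k w, (k+1) w)}; the paper bins movements into 5 um intervals.
#'
#' @param d numeric distance(s), um, >= 0.
#' @param bin_width band width in um, > 0 (default 5).
#' @return integer 0-based band index, \code{floor(d / bin_width)}.
#' @export
distance_band <- function(d, bin_width = 5) {
  if (any(d < 0)) stop("distances must be non-negative")
  if (bin_width <= 0) stop("bin_width must be positive")
  as.integer(floor(d / bin_width))
}

#' Cortical region of the nearest cortex edge
#'
#' @param p point or matrix of points, um.
#' @param geom an \code{oocyte_geometry}.
#' @return character vector of region labels (label of the nearest edge's
#'   first vertex).
#' @export
nearest_cortex_region <- function(p, geom) {
  stopifnot(inherits(geom, "oocyte_geometry"))
  p <- .as_points(p)
  vapply(seq_len(nrow(p)), function(i)
    geom$region_labels[.nearest_edge(p[i, ], geom$cortex)], character(1))
}

#' Test whether points lie inside the cortex polygon
#'
#' Even-odd (ray casting) rule; boundary points count as inside.
#'
#' @inheritParams nearest_cortex_region
#' @param tol boundary tolerance in um.
#' @return logical vector.
#' @export
inside_cortex <- function(p, geom, tol = 1e-9) {
  stopifnot(inherits(geom, "oocyte_geometry"))
  p <- .as_points(p)
  v <- geom$cortex
  n <- nrow(v)
  j <- c(n, seq_len(n - 1L))
  # vectorised even-odd rule: crossings counted per point over all edges
  cnt <- integer(nrow(p))
  for (i in seq_len(n)) {
    ji <- j[i]
    y1 <- v[i, 2]; y2 <- v[ji, 2]
    crosses <- (y1 > p[, 2]) != (y2 > p[, 2])
    if (any(crosses)) {
      xi <- v[ji, 1] + (p[crosses, 2] - y2) * (v[i, 1] - v[ji, 1]) / (y1 - y2)
      cnt[crosses] <- cnt[crosses] + as.integer(p[crosses, 1] < xi)
    }
  }
  out <- (cnt %% 2L) == 1L
  if (tol > 0) {
    bd <- distance_to_cortex(p, geom) <= tol
    out <- out | bd
  }
  out
}

## ---- geometry JSON I/O -----------------------------------------------

#' Read / write geometry JSON
#'
#' The exchange format is a JSON object with keys \code{cortex} (list of
#' [x, y] pairs), \code{posterior_pole}, \code{ap_axis},
#' \code{region_labels} and \code{units} ("um").
#'
#' @param path file path.
#' @return \code{read_geometry} returns an \code{oocyte_geometry};
#'   \code{write_geometry} returns \code{path} invisibly.
#' @export
read_geometry <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  if (!is.null(obj$units) && !identical(obj$units, "um"))
    stop("geometry units must be 'um'")
  build_geometry(obj$cortex, obj$posterior_pole, obj$ap_axis,
                 obj$region_labels)
}

#' @rdname read_geometry
#' @param geom an \code{oocyte_geometry}.
#' @export
write_geometry <- function(geom, path) {
  stopifnot(inherits(geom, "oocyte_geometry"))
  obj <- list(cortex = unname(geom$cortex),
              posterior_pole = geom$posterior_pole,
              ap_axis = geom$ap_axis,
              region_labels = geom$region_labels,
              units = "um")
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

## ---- internal helpers ------------------------------------------------

.as_points <- function(p) {
  if (is.null(dim(p))) {
    if (length(p) != 2L) stop("a point must have two coordinates")
    p <- matrix(as.numeric(p), ncol = 2L)
  } else {
    p <- as.matrix(p)
    storage.mode(p) <- "double"
  }
  if (!all(is.finite(p))) stop("point coordinates must be finite")
  p
}

# edge table: one row per edge (x1, y1, x2, y2)
.edges <- function(v) {
  n <- nrow(v)
  nxt <- c(seq_len(n)[-1L], 1L)
  cbind(v[, 1], v[, 2], v[nxt, 1], v[nxt, 2])
}

# vectorised point-to-segment distances for one point against all edges
.point_segment_dist <- function(px, py, e) {
  dx <- e[, 3] - e[, 1]
  dy <- e[, 4] - e[, 2]
  len2 <- dx * dx + dy * dy
  t <- ((px - e[, 1]) * dx + (py - e[, 2]) * dy) / pmax(len2, .Machine$double.eps)
  t <- pmin(pmax(t, 0), 1)
  qx <- e[, 1] + t * dx
  qy <- e[, 2] + t * dy
  sqrt((px - qx)^2 + (py - qy)^2)
}

.nearest_edge <- function(p, v) {
  which.min(.point_segment_dist(p[1], p[2], .edges(v)))
}

# closest point on the polygon boundary, plus the edge index
.nearest_boundary_point <- function(p, v) {
  e <- .edges(v)
  dx <- e[, 3] - e[, 1]
  dy <- e[, 4] - e[, 2]
  len2 <- pmax(dx * dx + dy * dy, .Machine$double.eps)
  t <- ((p[1] - e[, 1]) * dx + (p[2] - e[, 2]) * dy) / len2
  t <- pmin(pmax(t, 0), 1)
  qx <- e[, 1] + t * dx
  qy <- e[, 2] + t * dy
  d2 <- (p[1] - qx)^2 + (p[2] - qy)^2
  i <- which.min(d2)
  list(point = c(qx[i], qy[i]), edge = i, dist = sqrt(d2[i]),
       tangent = c(dx[i], dy[i]) / sqrt(len2[i]))
}

# proper segment-crossing test between non-adjacent edges
.polygon_self_intersects <- function(v) {
  e <- .edges(v)
  n <- nrow(e)
  orient <- function(ax, ay, bx, by, cx, cy)
    sign((bx - ax) * (cy - ay) - (by - ay) * (cx - ax))
  for (i in seq_len(n - 1L)) {
    for (k in seq((i + 1L), n)) {
      # skip adjacent edges (share a vertex), incl. the 1..n wrap pair
      if (k == i + 1L || (i == 1L && k == n)) next
      o1 <- orient(e[i, 1], e[i, 2], e[i, 3], e[i, 4], e[k, 1], e[k, 2])
      o2 <- orient(e[i, 1], e[i, 2], e[i, 3], e[i, 4], e[k, 3], e[k, 4])
      o3 <- orient(e[k, 1], e[k, 2], e[k, 3], e[k, 4], e[i, 1], e[i, 2])
      o4 <- orient(e[k, 1], e[k, 2], e[k, 3], e[k, 4], e[i, 3], e[i, 4])
      if (o1 != o2 && o3 != o4) return(TRUE)
    }
  }
  FALSE
}

# arc-length parameterisation of the cortex edges with region labels
.cortex_arcs <- function(geom) {
  e <- .edges(geom$cortex)
  len <- sqrt((e[, 3] - e[, 1])^2 + (e[, 4] - e[, 2])^2)
  data.frame(x1 = e[, 1], y1 = e[, 2], x2 = e[, 3], y2 = e[, 4],
             length = len, region = geom$region_labels,
             stringsAsFactors = FALSE)
}

# sample n points uniformly (by arc length) on edges with the given labels;
# returns points, inward normals and edge regions
.sample_cortex_points <- function(geom, n, regions = c("anterior", "lateral")) {
  arcs <- .cortex_arcs(geom)
  keep <- arcs$region %in% regions
  arcs <- arcs[keep, , drop = FALSE]
  if (nrow(arcs) == 0L) stop("no cortex edges with the requested labels")
  w <- arcs$length / sum(arcs$length)
  idx <- sample.int(nrow(arcs), n, replace = TRUE, prob = w)
  t <- stats::runif(n)
  px <- arcs$x1[idx] + t * (arcs$x2[idx] - arcs$x1[idx])
  py <- arcs$y1[idx] + t * (arcs$y2[idx] - arcs$y1[idx])
  tx <- (arcs$x2[idx] - arcs$x1[idx]) / arcs$length[idx]
  ty <- (arcs$y2[idx] - arcs$y1[idx]) / arcs$length[idx]
  # candidate normals; pick the one pointing toward the centroid
  nx <- -ty; ny <- tx
  cx <- geom$centroid[1] - px
  cy <- geom$centroid[2] - py
  flip <- (nx * cx + ny * cy) < 0
  nx[flip] <- -nx[flip]; ny[flip] <- -ny[flip]
  list(points = cbind(px, py), normals = cbind(nx, ny),
       region = arcs$region[idx])
}

# first exit of the ray p + s*d (s > 0) through the polygon boundary;
# returns the distance s (Inf if no crossing, which only happens for p
# outside or numerically on the boundary pointing outwards)
.ray_exit_distance <- function(p, d, geom) {
  e <- .edges(geom$cortex)
  ex <- e[, 3] - e[, 1]
  ey <- e[, 4] - e[, 2]
  denom <- d[1] * ey - d[2] * ex
  ok <- abs(denom) > 1e-12
  s <- ((e[, 1] - p[1]) * ey - (e[, 2] - p[2]) * ex) / denom
  u <- ((e[, 1] - p[1]) * d[2] - (e[, 2] - p[2]) * d[1]) / denom
  hit <- ok & s > 1e-9 & u >= 0 & u <= 1
  if (!any(hit)) return(Inf)
  min(s[hit])
}

# n points uniform over the polygon interior (rejection from bounding box)
.sample_interior_points <- function(geom, n) {
  v <- geom$cortex
  xr <- range(v[, 1]); yr <- range(v[, 2])
  out <- matrix(NA_real_, 0L, 2L)
  while (nrow(out) < n) {
    m <- max(2L * (n - nrow(out)), 16L)
    cand <- cbind(stats::runif(m, xr[1], xr[2]), stats::runif(m, yr[1], yr[2]))
    keep <- inside_cortex(cand, geom, tol = 0)
    out <- rbind(out, cand[keep, , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}
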