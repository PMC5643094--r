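#' Split a track table into per-track data.frames
#'
#' @param tracks a track table (columns \code{track_id, kind, frame, t_s,
#'   x_um, y_um}).
#' @return named list of per-track data.frames, in order of first
#'   appearance.
#' @export
split_tracks <- function(tracks) {
  .check_track_table(tracks)
  split(tracks, factor(tracks$track_id, levels = unique(tracks$track_id)))
}

.check_track_table <- function(tracks) {
  need <- c("track_id", "frame", "t_s", "x_um", "y_um")
  miss <- setdiff(need, names(tracks))
  if (length(miss))
    stop("track table is missing column(s): ", paste(miss, collapse = ", "))
  invisible(tracks)
}

#' Mean track speed
#'
#' The speed of a track is the mean of its instantaneous velocities at
#' individual time points, i.e. the mean over frames of step displacement
#' divided by step duration.
#'
#' @param track a single-track data.frame (columns \code{t_s, x_um, y_um}),
#'   at least 2 points.
#' @return speed in um/s.
#' @export
track_speed <- function(track) {
  n <- nrow(track)
  if (n < 2L) stop("track_speed needs at least 2 points")
  dx <- diff(track$x_um)
  dy <- diff(track$y_um)
  dt <- diff(track$t_s)
  if (any(dt <= 0)) stop("track times must be strictly increasing")
  mean(sqrt(dx^2 + dy^2) / dt)
}

#' Net direction of a track relative to the posterior pole
#'
#' Signed angle (degrees, in (-180, 180]) between the track's net
#' first-to-last displacement and the direction from the track's first
#' point toward the posterior pole.  0 means straight at the pole;
#' positive angles are counter-clockwise.
#'
#' @param track a single-track data.frame with nonzero net displacement.
#' @param geom an \code{oocyte_geometry}.
#' @return angle in degrees.
#' @export
net_angle <- function(track, geom) {
  if (nrow(track) < 2L) stop("net_angle needs at least 2 points")
  v <- c(track$x_um[nrow(track)] - track$x_um[1],
         track$y_um[nrow(track)] - track$y_um[1])
  if (all(v == 0)) stop("net_angle undefined for zero net displacement")
  u <- c(geom$posterior_pole[1] - track$x_um[1],
         geom$posterior_pole[2] - track$y_um[1])
  a <- (atan2(v[2], v[1]) - atan2(u[2], u[1])) * 180 / pi
  a <- ((a + 180) %% 360) - 180
  if (a == -180) a <- 180
  a
}

#' Comet lifespan
#'
#' @param track a single-track data.frame, at least 2 points.
#' @param frame_dt frame interval in s.
#' @return lifespan in s, \code{(n_frames - 1) * frame_dt}.
#' @export
comet_lifespan <- function(track, frame_dt) {
  if (nrow(track) < 2L) stop("comet_lifespan needs at least 2 points")
  (nrow(track) - 1L) * frame_dt
}

#' Per-track summary statistics
#'
#' Computes, for every track with at least \code{min_frames} points: mean
#' speed, net angle to the posterior (NA for zero net displacement),
#' distance of the first point from the pole, lifespan, net displacement
#' and the mobile flag.
#'
#' @param tracks a track table.
#' @param geom an \code{oocyte_geometry}.
#' @param min_frames minimum track length in frames (default 3, the
#'   conventional minimum for comet trackers).
#' @param mobile_threshold net displacement (um) above which a track counts
#'   as mobile (default 1).
#' @return data.frame with one row per retained track: \code{track_id,
#'   kind, n_frames, speed, net_angle, start_distance, lifespan,
#'   net_displacement, is_mobile}.
#' @export
track_stats <- function(tracks, geom, min_frames = 3L, mobile_threshold = 1) {
  stopifnot(inherits(geom, "oocyte_geometry"))
  trs <- split_tracks(tracks)
  trs <- trs[vapply(trs, nrow, 0L) >= min_frames]
  if (!length(trs)) stop("no tracks with >= min_frames points")
  n <- vapply(trs, nrow, 0L)
  first_x <- vapply(trs, function(tr) tr$x_um[1], 0)
  first_y <- vapply(trs, function(tr) tr$y_um[1], 0)
  last_x <- vapply(trs, function(tr) tr$x_um[nrow(tr)], 0)
  last_y <- vapply(trs, function(tr) tr$y_um[nrow(tr)], 0)
  disp <- sqrt((last_x - first_x)^2 + (last_y - first_y)^2)
  angle <- rep(NA_real_, length(trs))
  for (i in which(disp > 0)) angle[i] <- net_angle(trs[[i]], geom)
  out <- data.frame(
    track_id = vapply(trs, function(tr) tr$track_id[1], ""),
    kind = if ("kind" %in% names(tracks))
      vapply(trs, function(tr) tr$kind[1], "") else NA_character_,
    n_frames = n,
    speed = vapply(trs, track_speed, 0),
    net_angle = angle,
    start_distance = distance_to_posterior_pole(cbind(first_x, first_y),
                                                geom),
    lifespan = vapply(trs, function(tr) tr$t_s[nrow(tr)] - tr$t_s[1], 0),
    net_displacement = disp,
    is_mobile = disp >= mobile_threshold,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Fraction of posterior-directed tracks in a distance band
#'
#' Percentage of tracks whose net direction points into the posterior
#' half-plane (|net angle| < 90 degrees), among tracks with a defined net
#' angle whose start distance falls in \code{[band[1], band[2])} um from
#' the pole, with the binomial standard error.
#'
#' @param stats a \code{\link{track_stats}} table (or a track table plus
#'   \code{geom}).
#' @param band numeric length-2, half-open distance band in um.
#' @param geom required only when \code{stats} is a raw track table.
#' @return list with \code{percent}, \code{se} (both on the 0-100 scale)
#'   and \code{n}.
#' @export
posterior_fraction <- function(stats, band = c(0, 10), geom = NULL) {
  stats <- .as_track_stats(stats, geom)
  sel <- !is.na(stats$net_angle) &
    stats$start_distance >= band[1] & stats$start_distance < band[2]
  n <- sum(sel)
  if (n == 0L) stop("no angle-defined tracks in the requested band")
  p <- mean(abs(stats$net_angle[sel]) < 90)
  list(percent = 100 * p, se = 100 * sqrt(p * (1 - p) / n), n = n)
}

.as_track_stats <- function(stats, geom) {
  if (!is.null(stats$net_angle)) return(stats)
  if (is.null(geom)) stop("geom is required for raw track tables")
  track_stats(stats, geom)
}

#' Direction histogram in angular bins, by distance band
#'
#' Counts track net directions over half-open angular bins of
#' \code{interval} degrees (the circular histograms use 10 degree bins),
#' separately for each distance band from the posterior pole.
#'
#' @param stats a \code{\link{track_stats}} table or raw track table.
#' @param interval angular bin width in degrees; must divide 360.
#' @param bands numeric matrix/list of half-open [lo, hi) distance bands in
#'   um; default the three 10 um bands from the pole.
#' @param geom required for raw track tables.
#' @return matrix (bins x bands) of counts; bin rownames give the bin's
#'   lower edge in degrees on the [0, 360) circle (0 = toward the pole).
#' @export
direction_histogram <- function(stats, interval = 10,
                                bands = list(c(0, 10), c(10, 20), c(20, 30)),
                                geom = NULL) {
  if (360 %% interval != 0) stop("interval must divide 360")
  stats <- .as_track_stats(stats, geom)
  nb <- as.integer(360 / interval)
  edges <- seq(0, 360 - interval, by = interval)
  out <- matrix(0L, nrow = nb, ncol = length(bands),
                dimnames = list(edges,
                                vapply(bands, function(b)
                                  sprintf("%g-%g", b[1], b[2]), "")))
  ang <- stats$net_angle %% 360  # map (-180,180] onto [0,360)
  for (j in seq_along(bands)) {
    b <- bands[[j]]
    sel <- !is.na(stats$net_angle) &
      stats$start_distance >= b[1] & stats$start_distance < b[2]
    if (!any(sel)) next
    idx <- floor(ang[sel] / interval) + 1L
    tab <- tabulate(idx, nbins = nb)
    out[, j] <- tab
  }
  out
}

#' Relative frequency of track start positions by distance band
#'
#' Bins track start distances from the posterior pole into half-open bands
#' (default 5 um over 0-50 um) and returns relative frequencies that sum
#' to 1 over the included tracks.
#'
#' @param stats a \code{\link{track_stats}} table or raw track table.
#' @param bin band width in um.
#' @param range distance range \code{c(lo, hi)} in um; tracks outside it
#'   are dropped.
#' @param geom required for raw track tables.
#' @return data.frame with \code{band_lo, band_hi, n, frequency}.
#' @export
distance_binned_frequency <- function(stats, bin = 5, range = c(0, 50),
                                      geom = NULL) {
  stats <- .as_track_stats(stats, geom)
  d <- stats$start_distance
  d <- d[d >= range[1] & d < range[2]]
  nbins <- ceiling((range[2] - range[1]) / bin)
  idx <- distance_band(d - range[1], bin) + 1L
  n <- tabulate(idx, nbins = nbins)
  lo <- range[1] + bin * (seq_len(nbins) - 1L)
  data.frame(band_lo = lo, band_hi = lo + bin, n = n,
             frequency = if (sum(n) > 0) n / sum(n) else rep(0, nbins))
}

#' Mean comet speed by distance region
#'
#' Groups tracks by the distance of their first point from the posterior
#' pole (default regions 0-15 and 15-30 um) and reports per-region n, mean
#' speed and SEM.
#'
#' @param stats a \code{\link{track_stats}} table or raw track table.
#' @param regions list of half-open [lo, hi) regions in um.
#' @param geom required for raw track tables.
#' @return data.frame with \code{region, n, mean_speed, sem}.
#' @export
speed_by_region <- function(stats, regions = list(c(0, 15), c(15, 30)),
                            geom = NULL) {
  stats <- .as_track_stats(stats, geom)
  rows <- lapply(regions, function(r) {
    sel <- stats$start_distance >= r[1] & stats$start_distance < r[2]
    n <- sum(sel)
    if (n == 0L) stop(sprintf("no tracks in region [%g, %g)", r[1], r[2]))
    x <- stats$speed[sel]
    data.frame(region = sprintf("%g-%g", r[1], r[2]), n = n,
               mean_speed = mean(x),
               sem = stats::sd(x) / sqrt(n),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Growth speed by region from moving steps
#'
#' Region-stratified plus-end growth speed: instantaneous step speeds are
#' pooled over all tracks, each step assigned to the distance band of its
#' own starting point, and steps slower than \code{min_speed} (pauses -
#' static cortical comets) are excluded.  This is the natural readout for
#' comparing growth speeds between the posterior region and the cell
#' centre when tracks mix growth and cortical pausing.
#'
#' @param tracks a track table.
#' @param geom an \code{oocyte_geometry}.
#' @param regions list of half-open [lo, hi) distance bands from the
#'   posterior pole, um.
#' @param min_speed pause threshold, um/s (default 0.02).
#' @details Steps at a track's ends and steps bordering a pause are
#'   excluded: a sampling interval that brackets a growth-to-pause
#'   transition, a nucleation or a catastrophe covers only part of a
#'   growth interval, and its apparent speed is a biased mixture.
#' @return data.frame with \code{region, n} (steps), \code{mean_speed,
#'   sem}.
#' @export
growth_speed_by_region <- function(tracks, geom,
                                   regions = list(c(0, 15), c(15, 30)),
                                   min_speed = 0.02) {
  stopifnot(inherits(geom, "oocyte_geometry"))
  trs <- split_tracks(tracks)
  sp <- numeric(0); d0 <- numeric(0)
  for (tr in trs) {
    if (nrow(tr) < 4L) next
    v <- sqrt(diff(tr$x_um)^2 + diff(tr$y_um)^2) / diff(tr$t_s)
    moving <- v >= min_speed
    m <- length(v)
    ok <- moving &
      c(FALSE, moving[-m]) &       # previous step also moving
      c(moving[-1], FALSE)         # next step also moving
    if (!any(ok)) next
    sp <- c(sp, v[ok])
    d0 <- c(d0, distance_to_posterior_pole(
      cbind(tr$x_um[-nrow(tr)][ok], tr$y_um[-nrow(tr)][ok]), geom))
  }
  rows <- lapply(regions, function(r) {
    sel <- d0 >= r[1] & d0 < r[2]
    n <- sum(sel)
    if (n == 0L) stop(sprintf("no moving steps in region [%g, %g)",
                              r[1], r[2]))
    data.frame(region = sprintf("%g-%g", r[1], r[2]), n = n,
               mean_speed = mean(sp[sel]),
               sem = stats::sd(sp[sel]) / sqrt(n),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mobile fraction
#'
#' Percentage of tracks whose net first-to-last displacement is at least
#' \code{min_net_displacement} um, with the binomial standard error.
#'
#' @param stats a \code{\link{track_stats}} table or raw track table.
#' @param min_net_displacement threshold in um (> 0; default 1).
#' @param geom required for raw track tables.
#' @return list with \code{percent}, \code{se}, \code{n}.
#' @export
mobile_fraction <- function(stats, min_net_displacement = 1, geom = NULL) {
  if (min_net_displacement <= 0) stop("threshold must be positive")
  stats <- .as_track_stats(stats, geom)
  p <- mean(stats$net_displacement >= min_net_displacement)
  n <- nrow(stats)
  list(percent = 100 * p, se = 100 * sqrt(p * (1 - p) / n), n = n)
}

#' Test for an mRNP subpopulation moving at the microtubule growth speed
#'
#' Fits the oskar speed sample with (i) a single Gaussian and (ii) a
#' two-component Gaussian mixture in which one component's mean is pinned
#' to the mean EB1 (plus-end growth) speed, and reports the weight of the
#' pinned component together with a parametric-bootstrap likelihood-ratio
#' p-value for the presence of that subpopulation.
#'
#' @param oskar_speeds numeric vector of mRNP speeds (um/s), >= 50 values.
#' @param eb1_speeds numeric vector of comet speeds (um/s), >= 50 values
#'   (only the mean is used as the pinned component mean).
#' @param n_boot number of parametric bootstrap replicates for the LRT
#'   (default 99).
#' @param seed RNG seed for the bootstrap.
#' @return list of class \code{"subpop_test"}: \code{pinned_mean},
#'   \code{pinned_weight}, \code{lrt_stat}, \code{p_value}, plus the two
#'   fitted models.
#' @export
subpopulation_test <- function(oskar_speeds, eb1_speeds, n_boot = 99,
                               seed = 1L) {
  x <- as.numeric(oskar_speeds)
  if (length(x) < 50L || length(eb1_speeds) < 50L)
    stop("subpopulation_test needs at least 50 samples per group")
  if (stats::sd(x) == 0 || stats::sd(eb1_speeds) == 0)
    stop("degenerate (constant) speed sample")
  mu_pin <- mean(eb1_speeds)
  fit1 <- list(mean = mean(x), sd = stats::sd(x) * sqrt((length(x) - 1) /
                                                        length(x)))
  ll1 <- sum(stats::dnorm(x, fit1$mean, fit1$sd, log = TRUE))
  fit2 <- .fit_pinned_mixture(x, mu_pin)
  lrt <- 2 * (fit2$loglik - ll1)
  set.seed(as.integer(seed))
  boot <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    xb <- stats::rnorm(length(x), fit1$mean, fit1$sd)
    sb <- stats::sd(xb) * sqrt((length(xb) - 1) / length(xb))
    llb1 <- sum(stats::dnorm(xb, mean(xb), sb, log = TRUE))
    llb2 <- .fit_pinned_mixture(xb, mu_pin)$loglik
    boot[b] <- 2 * (llb2 - llb1)
  }
  p <- (1 + sum(boot >= lrt)) / (n_boot + 1)
  structure(list(pinned_mean = mu_pin, pinned_weight = fit2$weight,
                 lrt_stat = lrt, p_value = p,
                 fit_null = c(fit1, loglik = ll1), fit_mixture = fit2),
            class = "subpop_test")
}

#' @export
print.subpop_test <- function(x, ...) {
  cat("Speed-subpopulation mixture test\n")
  cat(sprintf("  pinned component mean : %.3f um/s\n", x$pinned_mean))
  cat(sprintf("  pinned weight         : %.3f\n", x$pinned_weight))
  cat(sprintf("  LRT statistic         : %.2f (bootstrap p = %.3g)\n",
              x$lrt_stat, x$p_value))
  invisible(x)
}

# EM fit of w*N(mu_pin, s1) + (1-w)*N(mu2, s2) with mu_pin fixed
.fit_pinned_mixture <- function(x, mu_pin, max_iter = 500, tol = 1e-8) {
  n <- length(x)
  w <- 0.5
  mu2 <- mean(x)
  s1 <- s2 <- max(stats::sd(x), 1e-6)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    d1 <- w * stats::dnorm(x, mu_pin, s1)
    d2 <- (1 - w) * stats::dnorm(x, mu2, s2)
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    g <- d1 / tot
    ll <- sum(log(tot))
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
    sw <- sum(g)
    w <- min(max(sw / n, 1e-6), 1 - 1e-6)
    s1 <- sqrt(max(sum(g * (x - mu_pin)^2) / max(sw, 1e-12), 1e-8))
    mu2 <- sum((1 - g) * x) / max(n - sw, 1e-12)
    s2 <- sqrt(max(sum((1 - g) * (x - mu2)^2) / max(n - sw, 1e-12), 1e-8))
  }
  list(weight = w, sd_pinned = s1, mean_free = mu2, sd_free = s2,
       loglik = ll_old)
}

#' Two-group comparison with the paper's test-selection rule
#'
#' Screens both groups for normality (Shapiro-Wilk at alpha = 0.05; samples
#' larger than 5000 are subsampled for the screen), then: both normal ->
#' F-test variance screen selects the Student or Welch t-test; otherwise
#' the Wilcoxon rank-sum test.  All three tests are reported for
#' transparency, along with which one the rule selected.
#'
#' @param sample_a,sample_b numeric vectors, >= 3 values each.
#' @param alpha screening level (default 0.05).
#' @return list of class \code{"group_comparison"}: \code{selected} (one of
#'   \code{"student_t"}, \code{"welch_t"}, \code{"rank_sum"}),
#'   \code{statistic}, \code{p_value}, and a \code{tests} data.frame with
#'   all three tests.
#' @export
compare_groups <- function(sample_a, sample_b, alpha = 0.05) {
  a <- as.numeric(sample_a); b <- as.numeric(sample_b)
  if (length(a) < 3L || length(b) < 3L)
    stop("compare_groups needs at least 3 values per group")
  shapiro_p <- function(x) {
    if (length(x) > 5000L) x <- sample(x, 5000L)
    if (stats::sd(x) == 0) return(0)  # degenerate: treat as non-normal
    stats::shapiro.test(x)$p.value
  }
  normal <- shapiro_p(a) > alpha && shapiro_p(b) > alpha
  equal_var <- if (normal) stats::var.test(a, b)$p.value > alpha else NA
  tt <- stats::t.test(a, b, var.equal = TRUE)
  wt <- stats::t.test(a, b, var.equal = FALSE)
  rs <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))
  tests <- data.frame(
    test = c("student_t", "welch_t", "rank_sum"),
    statistic = c(tt$statistic, wt$statistic, rs$statistic),
    p_value = c(tt$p.value, wt$p.value, rs$p.value),
    stringsAsFactors = FALSE)
  selected <- if (!normal) "rank_sum"
              else if (isTRUE(equal_var)) "student_t" else "welch_t"
  sel <- tests[tests$test == selected, ]
  structure(list(selected = selected, statistic = sel$statistic,
                 p_value = sel$p_value, normal = normal,
                 equal_variance = equal_var, tests = tests),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Two-group comparison\n")
  cat(sprintf("  selected test : %s (stat = %.3f, p = %.3g)\n",
              x$selected, x$statistic, x$p_value))
  print(x$tests, row.names = FALSE)
  invisible(x)
}
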