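test_that("cortex track selection applies the contact and angle rules", {
  geom <- std_geom()
  # a track that never comes within 1 um of the cortex: no event
  far <- straight_track(c(0, 0), 0, 0.3, 10)
  expect_equal(nrow(select_cortex_tracks(far, geom)), 0)

  # a straight track hitting the cortex nearly perpendicularly
  hit <- straight_track(c(0, 0), 0, 1.0, 26, id = "hit")
  ev <- select_cortex_tracks(hit, geom)
  expect_equal(nrow(ev), 1)
  expect_gt(ev$approach_angle, 80)
  expect_identical(ev$cortex_region, "posterior")

  # a track grazing nearly parallel to the cortex is excluded
  nb <- oocytemt:::.nearest_boundary_point(c(0, 19.9), geom$cortex)
  tang_deg <- atan2(nb$tangent[2], nb$tangent[1]) * 180 / pi
  graze <- straight_track(c(0, 19.2), tang_deg + 5, 0.3, 10, id = "graze")
  expect_equal(nrow(select_cortex_tracks(graze, geom)), 0)
})

test_that("dwell time is end time minus first qualifying contact time", {
  geom <- std_geom()
  # contact at t = 10.2 s, disappearance at t = 25.5 s -> 15.3 s:
  # approach the posterior cortex (pole vertex at x = 25), entering the
  # 1 um contact band at frame 6, then sit still until frame 15
  xs <- c(seq(17, 22, by = 1), rep(24.2, 10))
  tr <- data.frame(track_id = "d1", kind = "eb1",
                   frame = seq_along(xs) - 1,
                   t_s = (seq_along(xs) - 1) * 1.7,
                   x_um = xs, y_um = 0, stringsAsFactors = FALSE)
  ev <- select_cortex_tracks(tr, geom)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$end_time - ev$contact_time, ev$dwell)
  expect_equal(dwell_time(ev), ev$dwell)
  expect_equal(ev$contact_time, 10.2)
  expect_equal(ev$dwell, 15.3)

  # contact on the final frame -> dwell 0
  tr0 <- tr[1:7, ]
  ev0 <- select_cortex_tracks(tr0, geom)
  expect_equal(ev0$dwell, 0)
})

test_that("dwell pipeline matches the brute-force scan event-for-event", {
  geom <- std_geom()
  p <- eb1_params(n_comets = 100, hazard_far = 0.03, hazard_near = 0.03,
                  max_frames = 300)
  tracks <- generate_eb1_tracks(p, geom, seed = 51)
  fast <- select_cortex_tracks(tracks, geom)
  slow <- brute_dwell_events(tracks, geom)
  expect_identical(fast$track_id, slow$track_id)
  expect_equal(fast$contact_time, slow$contact_time, tolerance = 1e-9)
  expect_equal(fast$dwell, slow$dwell, tolerance = 1e-9)
  expect_identical(fast$cortex_region, slow$cortex_region)
  expect_equal(fast$approach_angle, slow$approach_angle, tolerance = 1e-9)
})

test_that("dwell values are invariant under rigid motion", {
  geom <- std_geom()
  tracks <- generate_eb1_tracks(
    eb1_params(n_comets = 60, hazard_far = 0, hazard_near = 0,
               max_frames = 300), geom, seed = 52)
  ev <- select_cortex_tracks(tracks, geom)
  phi <- 0.6
  R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2)
  shift <- c(7, -4)
  geom2 <- build_geometry(
    sweep(geom$cortex %*% t(R), 2, -shift),
    as.numeric(R %*% geom$posterior_pole) + shift,
    as.numeric(R %*% geom$ap_axis), geom$region_labels)
  xy <- cbind(tracks$x_um, tracks$y_um) %*% t(R)
  tracks2 <- tracks
  tracks2$x_um <- xy[, 1] + shift[1]
  tracks2$y_um <- xy[, 2] + shift[2]
  ev2 <- select_cortex_tracks(tracks2, geom2)
  expect_identical(ev2$track_id, ev$track_id)
  expect_equal(ev2$dwell, ev$dwell, tolerance = 1e-9)
})

test_that("generator pause hazard is recovered as mean dwell", {
  geom <- std_geom()
  h <- 1 / 10
  p <- eb1_params(n_comets = 700, hazard_far = 0, hazard_near = 0,
                  pause_hazard_posterior = h, pause_hazard_lateral = h,
                  max_frames = 500)
  tracks <- generate_eb1_tracks(p, geom, seed = 53)
  ev <- select_cortex_tracks(tracks, geom)
  expect_gt(nrow(ev), 200)
  se <- sd(ev$dwell) / sqrt(nrow(ev))
  # mean dwell -> 1/h, up to frame discretisation (< frame_dt)
  expect_lt(abs(mean(ev$dwell) - 1 / h), 3 * se + 1.7)
})

test_that("location-scale t fit recovers known parameters", {
  set.seed(54)
  x <- 15 + 4 * rt(10000, df = 5)
  fit <- fit_t_location_scale(x)
  expect_lt(abs(fit$mu - 15) / 15, 0.05)
  expect_lt(abs(fit$sigma - 4) / 4, 0.10)
  expect_lt(abs(fit$nu - 5) / 5, 0.10)
  expect_false(fit$at_bound)
  expect_equal(unname(coef(fit)), c(fit$mu, fit$sigma, fit$nu))

  # agrees with an independent ML implementation
  m <- suppressWarnings(
    MASS::fitdistr(x, "t", start = list(m = median(x), s = mad(x), df = 5)))
  expect_equal(fit$mu, unname(m$estimate["m"]), tolerance = 1e-3)
  expect_equal(fit$sigma, unname(m$estimate["s"]), tolerance = 1e-3)
  expect_equal(fit$nu, unname(m$estimate["df"]), tolerance = 1e-2)

  # normal sample: nu runs to large values or the bound
  set.seed(55)
  xn <- rnorm(5000, 10, 2)
  fn <- fit_t_location_scale(xn)
  expect_true(fn$nu > 50 || fn$at_bound)

  expect_error(fit_t_location_scale(rnorm(5)), "at least 10")
  expect_error(fit_t_location_scale(rep(1, 20)), "degenerate")
})

test_that("region comparison reports means, maxima and the rank-sum test", {
  set.seed(56)
  d <- rexp(60, 1 / 12)
  same <- compare_regions(d, d)
  expect_equal(unname(same$mean["posterior"] - same$mean["lateral"]), 0)
  expect_gt(same$rank_sum_p, 0.99)

  dp <- rexp(150, 1 / 15)
  dl <- rexp(150, 1 / 8)
  cmp <- compare_regions(dp, dl)
  expect_lt(abs(cmp$mean["posterior"] - 15), 3 * 15 / sqrt(150))
  expect_lt(abs(cmp$mean["lateral"] - 8), 3 * 8 / sqrt(150))
  expect_lt(cmp$rank_sum_p, 1e-6)
  expect_s3_class(cmp$fit_posterior, "tls_fit")

  expect_error(compare_regions(dp, dl[1:2]), "at least 3")
})

test_that("kymographs render static, moving and empty cases", {
  seg <- cbind(seq(0, 10, by = 1), 0)
  # one static comet for 20 frames: a single vertical line
  tr <- data.frame(track_id = "k1", kind = "eb1", frame = 0:19,
                   t_s = (0:19) * 1.7, x_um = 5, y_um = 0.2,
                   stringsAsFactors = FALSE)
  km <- render_kymograph(tr, seg, duration = 20 * 1.7)
  expect_equal(sum(km), 20)
  expect_equal(sum(rowSums(km) > 0), 1)
  expect_true(all(km[rowSums(km) > 0, ] == 1))

  # a comet moving parallel to the segment: a diagonal
  tr2 <- data.frame(track_id = "k2", kind = "eb1", frame = 0:9,
                    t_s = (0:9) * 1.7, x_um = seq(0.5, 9.5, by = 1),
                    y_um = 0.2, stringsAsFactors = FALSE)
  km2 <- render_kymograph(tr2, seg, duration = 10 * 1.7)
  expect_equal(sum(km2), 10)
  expect_equal(sum(rowSums(km2) > 0), 10)

  # empty track set: all-zero matrix
  empty <- tr[0, ]
  km0 <- render_kymograph(empty, seg, duration = 17)
  expect_true(all(km0 == 0))
})
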