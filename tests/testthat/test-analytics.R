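test_that("track speed is the mean of per-step velocities", {
  tr <- straight_track(c(0, 0), 0, 0.36, 10, dt = 1.7)
  expect_equal(track_speed(tr), 0.36, tolerance = 1e-12)

  two <- data.frame(t_s = c(0, 1, 2), x_um = c(0, 0.2, 0.6), y_um = 0)
  expect_equal(track_speed(two), 0.3, tolerance = 1e-12)

  set.seed(31)
  rnd <- data.frame(t_s = cumsum(runif(50, 0.5, 2)),
                    x_um = cumsum(rnorm(50)), y_um = cumsum(rnorm(50)))
  expect_equal(track_speed(rnd), brute_speed(rnd), tolerance = 1e-12)

  expect_error(track_speed(rnd[1, ]), "at least 2")
})

test_that("net angle is measured from the direction to the pole", {
  geom <- std_geom()
  # straight at the pole from the centre
  at_pole <- straight_track(c(0, 0), 0, 0.3, 5)
  expect_equal(net_angle(at_pole, geom), 0, tolerance = 1e-9)
  # straight away
  away <- straight_track(c(0, 0), 180, 0.3, 5)
  expect_equal(abs(net_angle(away, geom)), 180, tolerance = 1e-9)
  # perpendicular-left of the pole direction (pole is at +x from origin)
  left <- straight_track(c(0, 0), 90, 0.3, 5)
  expect_equal(net_angle(left, geom), 90, tolerance = 1e-9)
  # zero net displacement is signalled
  still <- data.frame(t_s = 0:3, x_um = c(0, 1, 1, 0), y_um = c(0, 0, 1, 0))
  expect_error(net_angle(still, geom), "zero net displacement")
})

test_that("speed is invariant under rigid motion of the points", {
  set.seed(32)
  tr <- data.frame(t_s = 0:29, x_um = cumsum(rnorm(30)),
                   y_um = cumsum(rnorm(30)))
  phi <- 1.1
  R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2)
  xy <- cbind(tr$x_um, tr$y_um) %*% t(R)
  tr2 <- data.frame(t_s = tr$t_s, x_um = xy[, 1] + 5, y_um = xy[, 2] - 3)
  expect_equal(track_speed(tr2), track_speed(tr), tolerance = 1e-12)
})

test_that("posterior fraction recovers known direction structure", {
  # all tracks aimed at the pole
  st <- fake_stats(net_angle = runif(50, -80, 80),
                   start_distance = runif(50, 0, 10))
  expect_equal(posterior_fraction(st, band = c(0, 10))$percent, 100)

  # isotropic null: 50% within 3 binomial SE
  set.seed(33)
  st2 <- fake_stats(net_angle = runif(10000, -180, 180),
                    start_distance = runif(10000, 0, 10))
  pf <- posterior_fraction(st2, band = c(0, 10))
  expect_lt(abs(pf$percent - 50), 3 * pf$se)

  # mirroring across the axis through the pole flips angle signs only
  st3 <- st2
  st3$net_angle <- -st3$net_angle
  expect_equal(posterior_fraction(st3, band = c(0, 10))$percent, pf$percent)

  expect_error(posterior_fraction(st2, band = c(90, 100)), "no angle")
})

test_that("posterior fraction round-trips the generator bias", {
  geom <- std_geom()
  tr <- generate_oskar_tracks(
    oskar_params(n_particles = 2000, mobile_fraction = 1,
                 bias_by_band = c(0.71, 0.71, 0.71)), geom, seed = 34)
  st <- track_stats(tr, geom)
  pf <- posterior_fraction(st, band = c(0, 10))
  expect_lt(abs(pf$percent - 71), 3 * pf$se)
})

test_that("direction histogram counts are a plain tally", {
  # 36 tracks at 5, 15, ..., 355 degrees: one per bin
  ang <- seq(5, 355, by = 10)
  ang <- ifelse(ang > 180, ang - 360, ang)  # map onto (-180, 180]
  st <- fake_stats(ang, start_distance = rep(2, 36))
  h <- direction_histogram(st)
  expect_true(all(h[, "0-10"] == 1L))
  expect_equal(sum(h), 36)

  # all at 0 degrees: a single bin
  st0 <- fake_stats(rep(0, 20), start_distance = rep(2, 20))
  h0 <- direction_histogram(st0)
  expect_equal(max(h0[, "0-10"]), 20)
  expect_equal(sum(h0), 20)

  # random angles: equals the brute-force tally, and counts are conserved
  set.seed(35)
  a <- runif(500, -180, 180)
  d <- runif(500, 0, 30)
  st1 <- fake_stats(a, d)
  h1 <- direction_histogram(st1)
  for (j in 1:3) {
    lo <- (j - 1) * 10; hi <- j * 10
    sel <- d >= lo & d < hi
    tal <- integer(36)
    for (x in a[sel] %% 360)
      tal[floor(x / 10) + 1] <- tal[floor(x / 10) + 1] + 1L
    expect_identical(unname(h1[, j]), tal)
  }
  expect_equal(sum(h1), sum(d < 30))
})

test_that("distance-binned frequencies sum to one and match the tally", {
  st <- fake_stats(rep(0, 30), start_distance = rep(2, 30))
  f <- distance_binned_frequency(st)
  expect_equal(f$frequency[1], 1)
  expect_lt(abs(sum(f$frequency) - 1), 1e-12)

  set.seed(36)
  d <- runif(10000, 0, 50)
  st2 <- fake_stats(rep(0, 10000), start_distance = d)
  f2 <- distance_binned_frequency(st2)
  se <- sqrt(0.1 * 0.9 / 10000)
  expect_true(all(abs(f2$frequency - 0.1) < 3 * se + 1e-12))
  tal <- integer(10)
  for (x in d) tal[floor(x / 5) + 1] <- tal[floor(x / 5) + 1] + 1L
  expect_identical(f2$n, tal)
  expect_lt(abs(sum(f2$frequency) - 1), 1e-12)
})

test_that("comet lifespan is (frames - 1) * dt", {
  expect_equal(comet_lifespan(straight_track(c(0, 0), 0, 0.2, 7), 1.7), 10.2)
  expect_equal(comet_lifespan(straight_track(c(0, 0), 0, 0.2, 2), 1.7), 1.7)
  expect_error(comet_lifespan(straight_track(c(0, 0), 0, 0.2, 2)[1, ], 1.7),
               "at least 2")
})

test_that("speed by region groups by start distance from the pole", {
  geom <- std_geom()
  tr <- rbind(straight_track(c(20, 0), 180, 0.23, 6, id = "near"),
              straight_track(c(0, 0), 180, 0.23, 6, id = "far"))
  sbr <- speed_by_region(tr, geom = geom)
  expect_equal(sbr$mean_speed, c(0.23, 0.23), tolerance = 1e-12)
  expect_equal(sbr$n, c(1L, 1L))

  # region assignment equals a brute-force distance test on start points
  tr2 <- generate_eb1_tracks(eb1_params(n_comets = 100), geom, seed = 37)
  st <- track_stats(tr2, geom)
  d0 <- st$start_distance
  sbr2 <- speed_by_region(st)
  expect_equal(sbr2$n[1], sum(d0 >= 0 & d0 < 15))
  expect_equal(sbr2$n[2], sum(d0 >= 15 & d0 < 30))
})

test_that("two-region speed generator round-trips", {
  geom <- std_geom()
  p <- eb1_params(n_comets = 800, v_far = 0.24, v_near = 0.18, v_sd = 0.02,
                  pause_hazard_posterior = 1e6, pause_hazard_lateral = 1e6)
  tr <- generate_eb1_tracks(p, geom, seed = 38)
  st <- track_stats(tr, geom)
  # bands clear of the 2 um logistic ramp around d_switch = 15
  far <- st[st$start_distance >= 20 & st$start_distance < 40, ]
  near <- st[st$start_distance < 10, ]
  expect_gt(nrow(far), 30)
  expect_gt(nrow(near), 10)
  se_f <- sd(far$speed) / sqrt(nrow(far))
  se_n <- sd(near$speed) / sqrt(nrow(near))
  expect_lt(abs(mean(far$speed) - 0.24), 3 * se_f)
  expect_lt(abs(mean(near$speed) - 0.18), 3 * se_n)
})

test_that("mobile fraction counts net displacements over the threshold", {
  st <- fake_stats(rep(0, 40), rep(5, 40), net_displacement = 0)
  expect_equal(mobile_fraction(st)$percent, 0)
  st2 <- fake_stats(rep(0, 40), rep(5, 40), net_displacement = 2)
  expect_equal(mobile_fraction(st2, min_net_displacement = 100)$percent, 0)
  expect_equal(mobile_fraction(st2, min_net_displacement = 1)$percent, 100)
  expect_error(mobile_fraction(st2, min_net_displacement = 0), "positive")

  geom <- std_geom()
  tr <- generate_oskar_tracks(oskar_params(n_particles = 2000,
                                           mobile_fraction = 0.12),
                              geom, seed = 39)
  mf <- mobile_fraction(track_stats(tr, geom, mobile_threshold = 0.5),
                        min_net_displacement = 0.5)
  expect_lt(abs(mf$percent - 12), 3 * mf$se)
})

test_that("subpopulation mixture test separates known models", {
  set.seed(40)
  eb <- rnorm(300, 0.23, 0.05)
  # no subpopulation at the plus-end growth speed
  osk1 <- rnorm(400, 0.47, 0.1)
  s1 <- subpopulation_test(osk1, eb, n_boot = 39, seed = 1)
  expect_lt(s1$pinned_weight, 0.05)
  # a 50/50 mixture is detected with weight about one half
  osk2 <- c(rnorm(200, 0.23, 0.05), rnorm(200, 0.47, 0.1))
  s2 <- subpopulation_test(osk2, eb, n_boot = 39, seed = 1)
  expect_lt(abs(s2$pinned_weight - 0.5), 0.1)
  expect_lt(s2$p_value, 0.05)
  expect_error(subpopulation_test(rep(0.3, 100), eb), "degenerate")
  expect_error(subpopulation_test(osk1[1:10], eb), "at least 50")
})

test_that("mixture LRT p-values are calibrated under the null", {
  set.seed(41)
  pv <- replicate(120, {
    x <- rnorm(100, 0.4, 0.1)
    eb <- rnorm(60, 0.23, 0.05)
    subpopulation_test(x, eb, n_boot = 39,
                       seed = sample.int(1e6, 1))$p_value
  })
  # bootstrap p-values sit on a lattice; ties are expected
  expect_gt(suppressWarnings(ks.test(pv, "punif"))$p.value, 0.01)
})

test_that("group comparison selects the paper's test hierarchy", {
  set.seed(42)
  a <- rnorm(100); b <- rnorm(100)
  r0 <- compare_groups(a, a)
  expect_gt(r0$tests$p_value[r0$tests$test == "rank_sum"], 0.99)

  r1 <- compare_groups(rnorm(100), rnorm(100, 2))
  expect_lt(r1$p_value, 1e-6)
  expect_true(r1$selected %in% c("student_t", "welch_t"))

  # heavy-tailed shifted samples select the rank-sum test
  h1 <- rt(200, df = 1.5)
  h2 <- rt(200, df = 1.5) + 2
  r2 <- compare_groups(h1, h2)
  expect_identical(r2$selected, "rank_sum")
  expect_error(compare_groups(1:2, 1:5), "at least 3")
})
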