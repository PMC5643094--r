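test_that("track generation is deterministic under a fixed seed", {
  geom <- std_geom()
  p <- eb1_params(n_comets = 40)
  t1 <- generate_eb1_tracks(p, geom, seed = 99)
  t2 <- generate_eb1_tracks(p, geom, seed = 99)
  expect_identical(t1, t2)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_tracks(t1, f1); write_tracks(t2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  o1 <- generate_oskar_tracks(oskar_params(n_particles = 40), geom, seed = 5)
  o2 <- generate_oskar_tracks(oskar_params(n_particles = 40), geom, seed = 5)
  expect_identical(o1, o2)
})

test_that("noise-free comets advance by v * dt per frame", {
  geom <- std_geom()
  p <- eb1_params(n_comets = 30, v_far = 0.23, v_near = 0.23, v_sd = 0,
                  hazard_far = 0, hazard_near = 0, censor_slope = 0,
                  heading_sd = 0, max_frames = 10)
  tr <- generate_eb1_tracks(p, geom, seed = 2)
  steps <- unlist(lapply(split_tracks(tr), function(t)
    sqrt(diff(t$x_um)^2 + diff(t$y_um)^2)))
  # every free-growth step is exactly v * dt; steps clamped at the cortex
  # (or paused there) are shorter
  full <- 0.23 * 1.7
  expect_true(all(steps <= full + 1e-9))
  expect_gt(mean(abs(steps - full) < 1e-9), 0.9)
})

test_that("comet lifetimes follow the frame-discretised exponential law", {
  geom <- std_geom()
  h <- 0.1
  # contact_dist = 0: no cortical pausing, lifetimes are hazard-only
  p <- eb1_params(n_comets = 4000, hazard_far = h, hazard_near = h,
                  censor_slope = 0, contact_dist = 0)
  tr <- generate_eb1_tracks(p, geom, seed = 21)
  nframes <- vapply(split_tracks(tr), nrow, 0L)
  lif <- (nframes - 1L) * 1.7
  # frame-discretised Exp(h): extra frames are geometric with q = e^{-h dt}
  q <- exp(-h * 1.7)
  mean_disc <- 1.7 * q / (1 - q)
  se <- sd(lif) / sqrt(length(lif))
  expect_lt(abs(mean(lif) - mean_disc), 3 * se)
  # randomised PIT of the frame counts against the geometric law is uniform
  k <- nframes - 1L
  pgeo <- function(k) ifelse(k < 0, 0, 1 - q^(k + 1))
  set.seed(1)
  u <- pgeo(k - 1) + runif(length(k)) * (pgeo(k) - pgeo(k - 1))
  expect_gt(ks.test(u, "punif")$p.value, 0.01)
})

test_that("all generated points stay inside the cortex polygon", {
  geom <- std_geom()
  tr <- generate_eb1_tracks(eb1_params(n_comets = 100), geom, seed = 3)
  expect_true(all(inside_cortex(cbind(tr$x_um, tr$y_um), geom, tol = 1e-7)))
  ok <- generate_oskar_tracks(oskar_params(n_particles = 100), geom, seed = 4)
  expect_true(all(inside_cortex(cbind(ok$x_um, ok$y_um), geom, tol = 1e-7)))
})

test_that("oskar generator honours mobile fraction and direction bias", {
  geom <- std_geom()
  # mobile_fraction = 0: every track is static
  tr0 <- generate_oskar_tracks(oskar_params(n_particles = 60,
                                            mobile_fraction = 0),
                               geom, seed = 6)
  st0 <- track_stats(tr0, geom)
  expect_true(all(st0$net_displacement == 0))

  # bias 1 everywhere: every mobile track is posterior-directed
  tr1 <- generate_oskar_tracks(
    oskar_params(n_particles = 300, mobile_fraction = 1,
                 bias_by_band = 1), geom, seed = 7)
  st1 <- track_stats(tr1, geom)
  mob <- st1[st1$net_displacement > 0, ]
  expect_true(all(abs(mob$net_angle) < 90))
})

test_that("generated speeds round-trip through the speed estimator", {
  geom <- std_geom()
  p <- oskar_params(n_particles = 1500, mobile_fraction = 1,
                    speed_mean = 0.36, speed_sd = 0.1,
                    run_length_mean = 5)
  tr <- generate_oskar_tracks(p, geom, seed = 8)
  st <- track_stats(tr, geom)
  sp <- st$speed[st$net_displacement > 0]
  se <- sd(sp) / sqrt(length(sp))
  expect_lt(abs(mean(sp) - 0.36), 3 * se)
})

test_that("generator rejects invalid parameters", {
  expect_error(eb1_params(frame_dt = 0), "frame_dt")
  expect_error(eb1_params(v_far = -1), "speeds")
  expect_error(eb1_params(hazard_far = -0.1), "hazards")
  expect_error(oskar_params(mobile_fraction = 1.5), "probability")
  expect_error(oskar_params(bias_by_band = c(0.5, 2)), "probabilities")
})
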