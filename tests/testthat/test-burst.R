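test_that("max projection is the pointwise maximum across z", {
  z <- array(7, dim = c(3, 5, 4))
  expect_equal(max_project(z), matrix(7, 5, 4))

  z <- array(0, dim = c(5, 8, 8))
  z[3, 4, 6] <- 99
  mp <- max_project(z)
  expect_equal(mp[4, 6], 99)
  expect_equal(sum(mp), 99)

  set.seed(1)
  z <- array(rnorm(4 * 6 * 6), dim = c(4, 6, 6))
  mp <- max_project(z)
  for (k in 1:4) expect_true(all(mp >= z[k, , ]))

  expect_error(max_project(array(0, dim = c(0, 4, 4))),
               class = "synieg_validation")
})

test_that("pure-noise images yield no detections at SNR 5", {
  mask <- nucleus_mask(cell_geometry(image_shape = c(64, 64),
                                     nucleus_axes = c(18, 14), n_sites = 1))
  hits <- 0
  for (s in 1:100) {
    img <- withr::with_seed(s, matrix(rpois(64 * 64, 130), 64, 64) +
                              matrix(rnorm(64 * 64, sd = 3), 64, 64))
    if (nrow(detect_foci(img, mask)) > 0) hits <- hits + 1
  }
  expect_lte(hits, 1)  # <= 1% of frames
})

test_that("a single rendered focus is detected within 1 px of the truth", {
  mask <- nucleus_mask(cell_geometry(image_shape = c(64, 64),
                                     nucleus_axes = c(18, 14), n_sites = 1))
  x0 <- 35.3; y0 <- 29.6
  for (s in 1:20) {
    img <- withr::with_seed(s, {
      base <- spot_image(64, A = 115, x0 = x0, y0 = y0, sx = 1.3, sy = 1.3,
                         b = 130)   # SNR ~ 10 per pixel at the peak
      matrix(rpois(64 * 64, base), 64, 64)
    })
    det <- detect_foci(img, mask)
    expect_equal(nrow(det), 1)
    expect_lt(sqrt((det$x_px - x0)^2 + (det$y_px - y0)^2), 1.5)
  }
})

test_that("the Gaussian fit recovers a noiseless spot to analytic accuracy", {
  img <- spot_image(21, A = 100, x0 = 11, y0 = 11, sx = 1.5, sy = 1.5,
                    b = 10)
  f <- fit_gaussian2d(img, c(11, 11))
  expect_true(f$converged)
  expect_equal(f$amplitude, 100, tolerance = 1e-6)
  expect_equal(f$sigma, c(1.5, 1.5), tolerance = 1e-6)
  expect_equal(f$background, 10, tolerance = 1e-4)
  I_true <- 2 * pi * 100 * 1.5^2     # 1413.717
  expect_lt(abs(f$integrated_intensity - I_true) / I_true, 1e-4)
})

test_that("a flat image gives a non-converged fit, not a zero burst", {
  img <- matrix(10, 21, 21)
  f <- fit_gaussian2d(img, c(11, 11))
  expect_false(f$converged)
  expect_true(is.na(f$integrated_intensity))
})

test_that("the integrated intensity absorbs constant offsets into the background", {
  img <- spot_image(21, A = 80, x0 = 10.4, y0 = 11.7, sx = 1.2, sy = 1.6,
                    b = 25)
  f0 <- fit_gaussian2d(img, c(10, 12))
  for (off in c(4, 8, 16)) {  # up to 20% of amplitude
    f1 <- fit_gaussian2d(img + off, c(10, 12))
    expect_lt(abs(f1$integrated_intensity - f0$integrated_intensity) /
                f0$integrated_intensity, 1e-3)
    expect_equal(f1$background, f0$background + off, tolerance = 1e-3)
  }
})

test_that("the fit is equivariant to integer translations", {
  big <- matrix(10, 41, 41)
  add_spot <- function(img, x0, y0) {
    xm <- matrix(seq_len(41), 41, 41, byrow = TRUE)
    ym <- matrix(seq_len(41), 41, 41)
    img + 90 * exp(-(xm - x0)^2 / (2 * 1.4^2) - (ym - y0)^2 / (2 * 1.4^2))
  }
  f1 <- fit_gaussian2d(add_spot(big, 15.3, 18.6), c(15, 19))
  f2 <- fit_gaussian2d(add_spot(big, 25.3, 28.6), c(25, 29))
  expect_equal(f1$integrated_intensity, f2$integrated_intensity,
               tolerance = 1e-6)
  expect_equal(f2$center - f1$center, c(10, 10), tolerance = 1e-6)
})

test_that("stationary spots give one track per site covering the movie", {
  det <- lapply(1:30, function(f)
    data.frame(x_px = c(20, 40), y_px = c(20, 35), score = c(5, 4)))
  tracks <- track_foci(det)
  expect_length(tracks, 2)
  for (tr in tracks) expect_equal(tr$frames_present, 30)
  pos <- sort(sapply(tracks, function(tr) tr$mean_position[1]))
  expect_equal(pos, c(20, 40))
})

test_that("distant detections are never merged and gaps are bridged", {
  # two sites 20 px apart, site 2 missing on frames 10-12
  det <- lapply(1:30, function(f) {
    d <- data.frame(x_px = c(20, 40), y_px = c(20, 20), score = c(5, 4))
    if (f %in% 10:12) d <- d[1, ]
    d
  })
  tracks <- track_foci(det)
  expect_length(tracks, 2)
  fp <- sort(sapply(tracks, `[[`, "frames_present"))
  expect_equal(fp, c(27, 30))

  # a 10-frame dropout exceeds the gap limit: the site reappears as a new track
  det2 <- lapply(1:40, function(f) {
    d <- data.frame(x_px = 20, y_px = 20, score = 5)
    if (f %in% 15:28) d <- d[0, ]
    d
  })
  expect_length(track_foci(det2), 2)
  expect_length(track_foci(det2, max_gap_frames = 20), 1)
})

test_that("empty detection input gives empty output", {
  expect_length(track_foci(list()), 0)
  expect_length(track_foci(lapply(1:5, function(f)
    data.frame(x_px = numeric(0), y_px = numeric(0), score = numeric(0)))), 0)
})

test_that("burst traces are ~0 on a background-only movie and linear in brightness", {
  sig <- quick_signals("starve")
  params <- kinetic_params(p_basal_yfp = 0, p_basal_dgfp = 0)
  traj <- simulate_circuit(circuit_preset("fos_btg2", n_sites = 2),
                           params, sig)
  traj <- traj[1:25, ]
  class(traj) <- c("trajectory", "data.frame")
  attr(traj, "dt_min") <- 2; attr(traj, "stim_onset_min") <- 10
  geom <- cell_geometry(image_shape = c(64, 64), nucleus_axes = c(18, 14),
                        n_sites = 2, seed = 3)
  movie <- render_movie(traj, geom, optics_noise(), seed = 9)
  forced <- list(structure(list(site_id = 1, frame = 1, x_px = 32, y_px = 32,
                                score = 0, mean_position = c(32, 32),
                                frames_present = 1),
                           class = "focus_track"))
  b <- burst_traces(movie, forced)
  v <- b$traces[[1]]$values
  v <- v[!is.na(v)]
  expect_gt(length(v), 5)
  # mean background "burst" is small compared to a real focus (~thousands)
  expect_lt(mean(v), 150)
})

test_that("two sites with doubled transcription give a doubled fitted trace", {
  sig <- quick_signals("serum10")
  traj <- simulate_circuit(circuit_preset("fos_btg2", n_sites = 2),
                           signals = sig)
  keep <- traj$time_min >= 30 & traj$time_min <= 50
  tr <- traj[keep, ]
  tr$T_site2 <- 2 * tr$T_site1   # impose the 2x relation
  class(tr) <- c("trajectory", "data.frame")
  attr(tr, "dt_min") <- 2; attr(tr, "stim_onset_min") <- 10
  geom <- cell_geometry(image_shape = c(64, 64), nucleus_axes = c(18, 14),
                        site_positions = data.frame(x_px = c(24, 40),
                                                    y_px = c(32, 32),
                                                    z_um = c(0, 0)))
  movie <- render_movie(tr, geom, optics_noise(poisson_noise = FALSE,
                                               read_noise_sd = 0), seed = 1)
  mk_track <- function(id, x) structure(
    list(site_id = id, frame = 1, x_px = x, y_px = 32, score = 0,
         mean_position = c(x, 32), frames_present = 1),
    class = "focus_track")
  b <- burst_traces(movie, list(mk_track(1, 24), mk_track(2, 40)))
  r <- b$traces[[2]]$values / b$traces[[1]]$values
  expect_true(all(abs(r - 2) < 0.1))
})

test_that("channel-role mismatch is reported", {
  sm <- small_movie(seed = 1, t_max = 20)
  movie <- sm$movie
  movie$channel_roles <- c("H2B", "FISH", "YFP")
  expect_error(burst_traces(movie, list()), class = "synieg_validation")
  expect_error(movie_slab(movie, 1, "MCP"), class = "synieg_validation")
})
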