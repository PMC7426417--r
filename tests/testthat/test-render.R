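test_that("rendering is bit-identical under a fixed seed", {
  a <- small_movie(seed = 5, t_max = 30)
  b <- small_movie(seed = 5, t_max = 30)
  c <- small_movie(seed = 6, t_max = 30)
  expect_identical(a$movie$data, b$movie$data)
  expect_false(identical(a$movie$data, c$movie$data))
})

test_that("a zero trajectory renders background-only MCP frames", {
  sig <- quick_signals("starve")
  params <- kinetic_params(p_basal_yfp = 0, p_basal_dgfp = 0)
  traj <- simulate_circuit(circuit_preset("fos_btg2", n_sites = 4),
                           params, sig)
  traj <- traj[1:10, ]
  class(traj) <- c("trajectory", "data.frame")
  attr(traj, "dt_min") <- 2; attr(traj, "stim_onset_min") <- 10
  geom <- cell_geometry(image_shape = c(64, 64), nucleus_axes = c(18, 14),
                        n_sites = 4, seed = 3)
  opt <- optics_noise()
  movie <- render_movie(traj, geom, opt, seed = 1)
  mask <- nucleus_mask(geom)
  img <- max_project(movie_slab(movie, 1, "MCP"))
  # no focus above the detection threshold anywhere
  expect_equal(nrow(detect_foci(img, mask)), 0)
  # frame mean ~ offset + background over the nucleus (max projection of 7
  # Poisson slices sits above the single-slice mean, within a few sds)
  expect_lt(abs(mean(movie$data[1, 4, 2, , ][mask]) -
                  (opt$camera_offset + opt$mcp_nuclear_background_au +
                     opt$ambient_photons)), 3)
})

test_that("expected focus photons scale linearly with the gain", {
  sig <- quick_signals("serum10")
  traj <- simulate_circuit(circuit_preset("fos_btg2", n_sites = 2),
                           signals = sig)
  traj <- traj[traj$time_min >= 36 & traj$time_min <= 44, ]  # near peak
  class(traj) <- c("trajectory", "data.frame")
  attr(traj, "dt_min") <- 2; attr(traj, "stim_onset_min") <- 10
  geom <- cell_geometry(image_shape = c(64, 64), nucleus_axes = c(18, 14),
                        n_sites = 2, seed = 3)
  noiseless <- function(gain) {
    opt <- optics_noise(photons_per_au = gain, poisson_noise = FALSE,
                        read_noise_sd = 0, camera_offset = 0,
                        mcp_nuclear_background_au = 0, ambient_photons = 0)
    m <- render_movie(traj, geom, opt, seed = 1)
    sum(movie_slab(m, 1, "MCP"))
  }
  s1 <- noiseless(6000); s2 <- noiseless(12000)
  # camera quantization leaves a small rounding residue
  expect_equal(s2 / s1, 2, tolerance = 0.02)
})

test_that("collected focus photons are invariant to the site's z position", {
  sig <- quick_signals("serum10")
  traj <- simulate_circuit(circuit_preset("fos_btg2", n_sites = 1),
                           signals = sig)
  traj <- traj[traj$time_min == 40, , drop = FALSE]
  class(traj) <- c("trajectory", "data.frame")
  attr(traj, "dt_min") <- 2; attr(traj, "stim_onset_min") <- 10
  photons_at_z <- function(z_um) {
    geom <- cell_geometry(image_shape = c(64, 64), nucleus_axes = c(18, 14),
                          site_positions = data.frame(x_px = 32, y_px = 32,
                                                      z_um = z_um))
    opt <- optics_noise(poisson_noise = FALSE, read_noise_sd = 0,
                        camera_offset = 0, mcp_nuclear_background_au = 0,
                        ambient_photons = 0)
    m <- render_movie(traj, geom, opt, seed = 1)
    sum(m$data[1, , 2, , ])
  }
  ref <- photons_at_z(0)
  for (z in c(-2.4, -1.2, 1.2, 2.4))
    expect_equal(photons_at_z(z), ref, tolerance = 0.05)
})

test_that("channels are independent: YFP ignores transcription, MCP ignores protein", {
  sig <- quick_signals("serum10")
  base <- simulate_circuit(circuit_preset("fos_btg2", n_sites = 2),
                           signals = sig)
  keep <- base$time_min <= 20
  mk <- function(traj) {
    tr <- traj[keep, ]
    class(tr) <- c("trajectory", "data.frame")
    attr(tr, "dt_min") <- 2; attr(tr, "stim_onset_min") <- 10
    tr
  }
  t1 <- mk(base)
  t2 <- mk(transform(base, protein = protein * 3))
  t3 <- mk(base); t3$T_site1 <- t3$T_site1 * 3; t3$T_site2 <- t3$T_site2 * 3
  geom <- cell_geometry(image_shape = c(64, 64), nucleus_axes = c(18, 14),
                        n_sites = 2, seed = 3)
  opt <- optics_noise(poisson_noise = FALSE, read_noise_sd = 0)
  m1 <- render_movie(t1, geom, opt, seed = 1)
  m2 <- render_movie(t2, geom, opt, seed = 1)
  m3 <- render_movie(t3, geom, opt, seed = 1)
  expect_identical(m1$data[, , 2, , ], m2$data[, , 2, , ])  # MCP unchanged
  expect_identical(m1$data[, , 3, , ], m3$data[, , 3, , ])  # YFP unchanged
  expect_false(identical(m1$data[, , 3, , ], m2$data[, , 3, , ]))
  expect_false(identical(m1$data[, , 2, , ], m3$data[, , 2, , ]))
})

test_that("quantified focus intensity tracks the true transcription rate (noiseless)", {
  sm <- small_movie(seed = 2, optics = optics_noise(poisson_noise = FALSE,
                                                    read_noise_sd = 0))
  dt <- detect_and_track(sm$movie)
  expect_equal(length(dt$tracks), 4)
  b <- burst_traces(sm$movie, dt$tracks)
  Tm <- rowMeans(transcription_rates(sm$traj))
  mb <- mean_trace(b$traces)
  ok <- !is.na(mb$values)
  expect_gt(sum(ok), 20)
  expect_gt(cor(mb$values[ok], Tm[ok])^2, 0.99)
})

test_that("movie TIFF round trip is lossless including metadata", {
  sm <- small_movie(seed = 4, t_max = 24)
  path <- file.path(withr::local_tempdir(), "movie.tif")
  write_movie_tiff(sm$movie, path)
  back <- read_movie_tiff(path)
  expect_identical(back$data, sm$movie$data)
  expect_equal(back$channel_roles, sm$movie$channel_roles)
  expect_equal(back$dt_min, sm$movie$dt_min)
  expect_equal(back$z_step_um, 0.8)
  expect_equal(back$stim_onset_min, sm$movie$stim_onset_min)
  expect_equal(plain_df(back$ground_truth$trajectory),
               plain_df(sm$movie$ground_truth$trajectory),
               tolerance = 1e-12)
})

test_that("jittered populations honor cv and the seeding contract", {
  geom <- cell_geometry(n_sites = 4)
  base <- default_kinetic_params()
  expect_error(jitter_population(geom, base, 3, cv = -0.1, seed = 1),
               class = "synieg_validation")

  same <- jitter_population(geom, base, 5, cv = 0, seed = 1)
  for (cell in same) {
    expect_equal(cell$params, base)
    expect_equal(cell$geometry$site_positions, geom$site_positions)
  }

  p1 <- jitter_population(geom, base, 50, cv = 0.2, seed = 1)
  p2 <- jitter_population(geom, base, 50, cv = 0.2, seed = 1)
  p3 <- jitter_population(geom, base, 50, cv = 0.2, seed = 2)
  k1 <- sapply(p1, function(c) c$params$k_tx)
  k2 <- sapply(p2, function(c) c$params$k_tx)
  k3 <- sapply(p3, function(c) c$params$k_tx)
  expect_identical(k1, k2)
  expect_false(identical(k1, k3))
  cv_hat <- sd(k1) / mean(k1)
  expect_gt(cv_hat, 0.12); expect_lt(cv_hat, 0.28)
})

test_that("site/geometry validation catches bad placements", {
  expect_error(
    cell_geometry(image_shape = c(64, 64), nucleus_axes = c(18, 14),
                  site_positions = data.frame(x_px = 5, y_px = 5, z_um = 0)),
    class = "synieg_validation")
  expect_error(
    cell_geometry(image_shape = c(64, 64), nucleus_axes = c(18, 14),
                  site_positions = data.frame(x_px = c(30, 31),
                                              y_px = c(32, 32),
                                              z_um = c(0, 0))),
    class = "synieg_validation")
  expect_error(cell_geometry(image_shape = c(40, 40),
                             nucleus_axes = c(22, 18)),
               class = "synieg_validation")
})
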