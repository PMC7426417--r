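#' Render a simulated trajectory into a synthetic time-lapse stack
#'
#' Produces a T x Z x C x Y x X integer movie with three channels: a
#' uniform nuclear marker (`H2B`), the transcription-site channel (`MCP`)
#' with one punctate focus per integration site on a diffuse nuclear
#' background, and a diffuse reporter channel (`YFP`) whose nuclear fill
#' follows the protein trace. The z-stack has 7 slices spaced 0.8 um,
#' centred on the nucleus mid-plane.
#'
#' Focus `i` at frame `t` carries total expected photons
#' `photons_per_au * T_i(t)`, split across z-slices by a Gaussian axial
#' profile (normalized over the 7 acquired slices, so the collected focus
#' photon sum is independent of the site's z position) and spread in-plane
#' as a 2D Gaussian of width `psf_sigma_xy_px`. Expected photon images are
#' Poisson-sampled, Gaussian read noise and the camera offset are added,
#' and values are clipped to the camera bit depth. Rendering is
#' deterministic for a fixed `seed` (bit-identical stacks).
#'
#' @param traj A trajectory from [simulate_circuit()].
#' @param geom A [cell_geometry()]; its site count must match the
#'   trajectory's.
#' @param optics An [optics_noise()] model.
#' @param seed Integer seed for the photon noise.
#' @return An object of class `movie_stack`: list with `data`
#'   (T x Z x C x Y x X integer array), `channel_roles = c("H2B", "MCP",
#'   "YFP")`, `time_min`, `dt_min`, `z_step_um`, `pixel_size_um`, and
#'   `ground_truth` (the trajectory, geometry, optics and seed used).
#' @export
render_movie <- function(traj, geom, optics = optics_noise(), seed = 1) {
  if (!inherits(traj, "trajectory"))
    abort_validation("`traj` must be a trajectory")
  if (!inherits(geom, "cell_geometry"))
    abort_validation("`geom` must be a cell_geometry")
  if (!inherits(optics, "optics_noise"))
    abort_validation("`optics` must be an optics_noise model")
  Tmat <- transcription_rates(traj)
  n_sites <- ncol(Tmat)
  if (n_sites != nrow(geom$site_positions))
    abort_validation("trajectory has %d sites but geometry has %d",
                     n_sites, nrow(geom$site_positions))

  n_t <- nrow(traj); n_z <- 7L; n_c <- 3L
  ny <- geom$image_shape[1]; nx <- geom$image_shape[2]
  z_step <- 0.8
  z_um <- (seq_len(n_z) - (n_z + 1) / 2) * z_step
  mask <- nucleus_mask(geom)
  maxval <- 2^optics$bit_depth - 1

  # per-site axial weights, normalized over the acquired slices
  W <- sapply(seq_len(n_sites), function(i) {
    w <- exp(-(z_um - geom$site_positions$z_um[i])^2 /
               (2 * optics$psf_sigma_z_um^2))
    w / sum(w)
  })  # n_z x n_sites

  # per-site lateral PSF patch (constant across time and z)
  sxy <- optics$psf_sigma_xy_px
  half <- ceiling(4 * sxy) + 1L
  patches <- lapply(seq_len(n_sites), function(i) {
    x0 <- geom$site_positions$x_px[i]; y0 <- geom$site_positions$y_px[i]
    xs <- max(1L, floor(x0) - half):min(nx, floor(x0) + half)
    ys <- max(1L, floor(y0) - half):min(ny, floor(y0) + half)
    gx <- exp(-(xs - x0)^2 / (2 * sxy^2))
    gy <- exp(-(ys - y0)^2 / (2 * sxy^2))
    k <- outer(gy, gx) / (2 * pi * sxy^2)
    list(xs = xs, ys = ys, k = k)
  })

  h2b <- matrix(optics$ambient_photons, ny, nx)
  h2b[mask] <- h2b[mask] + optics$h2b_fill_photons
  mcp_bg <- matrix(optics$ambient_photons, ny, nx)
  mcp_bg[mask] <- mcp_bg[mask] + optics$mcp_nuclear_background_au

  P <- traj$protein
  saturated <- FALSE

  data <- withr::with_seed(as.integer(seed), {
    arr <- array(0L, dim = c(n_t, n_z, n_c, ny, nx))
    for (t in seq_len(n_t)) {
      yfp <- matrix(optics$ambient_photons, ny, nx)
      yfp[mask] <- yfp[mask] + optics$yfp_autofluorescence_au +
        optics$yfp_photons_per_au_px * P[t]
      for (z in seq_len(n_z)) {
        for (ch in seq_len(n_c)) {
          mu <- switch(ch, h2b, mcp_bg, yfp)
          if (ch == 2L) {
            mu <- mu  # copy-on-write below
            for (i in seq_len(n_sites)) {
              amp <- optics$photons_per_au * Tmat[t, i] * W[z, i]
              if (amp > 0) {
                p <- patches[[i]]
                mu[p$ys, p$xs] <- mu[p$ys, p$xs] + amp * p$k
              }
            }
          }
          if (max(mu) + optics$camera_offset > maxval) saturated <- TRUE
          img <- if (optics$poisson_noise)
            matrix(stats::rpois(length(mu), mu), ny, nx) else mu
          if (optics$read_noise_sd > 0)
            img <- img + matrix(stats::rnorm(length(img),
                                             sd = optics$read_noise_sd),
                                ny, nx)
          img <- round(img + optics$camera_offset)
          img[img < 0] <- 0; img[img > maxval] <- maxval
          arr[t, z, ch, , ] <- as.integer(img)
        }
      }
    }
    arr
  })
  if (saturated)
    warning("expected photons exceed the camera bit depth; foci saturate")

  structure(list(data = data,
                 channel_roles = c("H2B", "MCP", "YFP"),
                 time_min = traj$time_min,
                 dt_min = attr(traj, "dt_min") %||% diff(traj$time_min[1:2]),
                 z_step_um = z_step,
                 pixel_size_um = geom$pixel_size_um,
                 stim_onset_min = attr(traj, "stim_onset_min") %||% 0,
                 bit_depth = optics$bit_depth,
                 seed = seed,
                 ground_truth = list(trajectory = traj, geometry = geom,
                                     optics = optics, seed = seed)),
            class = "movie_stack")
}

channel_index <- function(movie, role) {
  i <- match(role, movie$channel_roles)
  if (is.na(i))
    abort_validation('channel role "%s" not present (have: %s)', role,
                     paste(movie$channel_roles, collapse = ", "))
  i
}

#' Extract one frame's z-slab of a channel
#' @param movie A `movie_stack`.
#' @param frame Frame index (1-based).
#' @param channel Channel role name.
#' @return A Z x Y x X numeric array.
#' @export
movie_slab <- function(movie, frame, channel = "MCP") {
  ci <- channel_index(movie, channel)
  movie$data[frame, , ci, , ]
}

#' Write / read a synthetic movie as multi-page TIFF
#'
#' Pages are written in TZCYX order (z fastest within channel within
#' frame... precisely: for each frame, for each z, for each channel). The
#' axis order and calibration are recorded both in the TIFF description and
#' in a JSON sidecar `<path>.json`; the ground-truth trajectory, if
#' attached, is written as `<path>.truth.csv`.
#'
#' @param movie A `movie_stack`.
#' @param path Output TIFF path.
#' @param write_truth Also write the ground-truth trajectory CSV.
#' @return `path`, invisibly (writer); a `movie_stack` (reader; ground
#'   truth is re-attached when the sidecar points to an existing CSV).
#' @export
write_movie_tiff <- function(movie, path, write_truth = TRUE) {
  d <- dim(movie$data)
  maxval <- 2^movie$bit_depth - 1
  pages <- vector("list", d[1] * d[2] * d[3])
  k <- 0L
  for (t in seq_len(d[1])) for (z in seq_len(d[2])) for (ch in seq_len(d[3])) {
    k <- k + 1L
    pages[[k]] <- movie$data[t, z, ch, , ] / maxval
  }
  meta <- list(axes = "TZCYX",
               shape = d,
               channel_roles = movie$channel_roles,
               dt_min = movie$dt_min,
               time_min = movie$time_min,
               z_step_um = movie$z_step_um,
               pixel_size_um = movie$pixel_size_um,
               stim_onset_min = movie$stim_onset_min,
               bit_depth = movie$bit_depth,
               seed = movie$seed)
  truth_csv <- paste0(path, ".truth.csv")
  if (write_truth && !is.null(movie$ground_truth$trajectory)) {
    write_trajectory_csv(movie$ground_truth$trajectory, truth_csv)
    meta$ground_truth_csv <- basename(truth_csv)
    meta$site_positions <- movie$ground_truth$geometry$site_positions
    meta$nucleus <- list(center = movie$ground_truth$geometry$nucleus_center,
                         axes = movie$ground_truth$geometry$nucleus_axes)
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none",
                  reduce = TRUE)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_movie_tiff
#' @export
read_movie_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- as.integer(meta$shape)
  maxval <- 2^meta$bit_depth - 1
  arr <- array(0L, dim = d)
  k <- 0L
  for (t in seq_len(d[1])) for (z in seq_len(d[2])) for (ch in seq_len(d[3])) {
    k <- k + 1L
    arr[t, z, ch, , ] <- as.integer(round(pages[[k]] * maxval))
  }
  gt <- NULL
  truth_csv <- file.path(dirname(path), meta$ground_truth_csv %||% "")
  if (!is.null(meta$ground_truth_csv) && file.exists(truth_csv)) {
    gt <- list(trajectory = read_trajectory_csv(truth_csv))
    if (!is.null(meta$site_positions)) {
      gt$geometry <- list(site_positions = as.data.frame(meta$site_positions),
                          nucleus_center = meta$nucleus$center,
                          nucleus_axes = meta$nucleus$axes,
                          image_shape = d[4:5])
    }
  }
  structure(list(data = arr,
                 channel_roles = meta$channel_roles,
                 time_min = meta$time_min,
                 dt_min = meta$dt_min,
                 z_step_um = meta$z_step_um,
                 pixel_size_um = meta$pixel_size_um,
                 stim_onset_min = meta$stim_onset_min %||% 0,
                 bit_depth = meta$bit_depth,
                 seed = meta$seed,
                 ground_truth = gt),
            class = "movie_stack")
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<movie_stack> %d frames x %d z x %d channels x %d x %d px (dt %g min)\n",
              d[1], d[2], d[3], d[4], d[5], x$dt_min))
  cat("  channels:", paste(x$channel_roles, collapse = ", "), "\n")
  invisible(x)
}
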