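#' Single-nucleus imaging geometry
#'
#' Defines the field of view, the elliptical nucleus and the in-nucleus
#' positions of the transcriptional integration sites for the synthetic
#' movie renderer. Pixel coordinates are 1-based with `x` the column and
#' `y` the row; site `z` positions are micrometres relative to the centre
#' of the z-stack.
#'
#' @param image_shape `c(Y, X)` image size in pixels.
#' @param pixel_size_um Pixel size (um/px).
#' @param nucleus_center `c(x, y)` in px; defaults to the image centre.
#' @param nucleus_axes `c(a, b)` semi-axes in px (x and y).
#' @param n_sites Number of integration sites to place (ignored when
#'   `site_positions` is given).
#' @param site_positions Optional data frame with columns `x_px`, `y_px`,
#'   `z_um`; positions must be strictly inside the nucleus and pairwise
#'   separated by at least `min_separation_px` in-plane.
#' @param min_separation_px Minimum in-plane site separation (px).
#' @param z_range_um Sites are sampled uniformly in `[-z_range_um, z_range_um]`.
#' @param margin_px Required margin between nucleus and image border.
#' @param seed Seed for site placement (required when sampling positions).
#' @return An object of class `cell_geometry`.
#' @export
cell_geometry <- function(image_shape = c(128, 128), pixel_size_um = 0.27,
                          nucleus_center = NULL, nucleus_axes = c(22, 18),
                          n_sites = 8, site_positions = NULL,
                          min_separation_px = 8, z_range_um = 1.2,
                          margin_px = 5, seed = 1) {
  if (length(image_shape) != 2L || any(image_shape < 16))
    abort_validation("`image_shape` must be c(Y, X), each >= 16")
  stopifnot_scalar_number(pixel_size_um, "pixel_size_um", min = 0)
  if (is.null(nucleus_center))
    nucleus_center <- c(image_shape[2] / 2, image_shape[1] / 2)
  a <- nucleus_axes[1]; b <- nucleus_axes[2]
  if (nucleus_center[1] - a < margin_px ||
      nucleus_center[1] + a > image_shape[2] - margin_px ||
      nucleus_center[2] - b < margin_px ||
      nucleus_center[2] + b > image_shape[1] - margin_px)
    abort_validation("nucleus must fit in the frame with a %d px margin",
                     margin_px)

  inside <- function(x, y, shrink = 1) {
    ((x - nucleus_center[1]) / (a * shrink))^2 +
      ((y - nucleus_center[2]) / (b * shrink))^2 < 1
  }

  if (is.null(site_positions)) {
    stopifnot_scalar_number(n_sites, "n_sites", min = 1)
    site_positions <- withr::with_seed(as.integer(seed), {
      pts <- matrix(numeric(0), ncol = 3)
      tries <- 0
      while (nrow(pts) < n_sites && tries < 10000) {
        tries <- tries + 1
        x <- nucleus_center[1] + stats::runif(1, -0.72, 0.72) * a
        y <- nucleus_center[2] + stats::runif(1, -0.72, 0.72) * b
        if (!inside(x, y, shrink = 0.9)) next
        if (nrow(pts) &&
            min(sqrt((pts[, 1] - x)^2 + (pts[, 2] - y)^2)) < min_separation_px)
          next
        z <- stats::runif(1, -z_range_um, z_range_um)
        pts <- rbind(pts, c(x, y, z))
      }
      if (nrow(pts) < n_sites)
        abort_validation("could not place %d sites with %g px separation",
                         n_sites, min_separation_px)
      data.frame(x_px = pts[, 1], y_px = pts[, 2], z_um = pts[, 3])
    })
  } else {
    site_positions <- as.data.frame(site_positions)
    if (!all(c("x_px", "y_px", "z_um") %in% names(site_positions)))
      abort_validation("`site_positions` needs columns x_px, y_px, z_um")
    if (!all(inside(site_positions$x_px, site_positions$y_px)))
      abort_validation("all sites must lie strictly inside the nucleus")
    if (nrow(site_positions) > 1) {
      d <- as.matrix(stats::dist(site_positions[, c("x_px", "y_px")]))
      diag(d) <- Inf
      if (min(d) < min_separation_px)
        abort_validation("sites must be >= %g px apart in-plane",
                         min_separation_px)
    }
  }

  structure(list(image_shape = as.integer(image_shape),
                 pixel_size_um = pixel_size_um,
                 nucleus_center = nucleus_center,
                 nucleus_axes = nucleus_axes,
                 site_positions = site_positions,
                 min_separation_px = min_separation_px),
            class = "cell_geometry")
}

#' Logical nucleus mask for a geometry
#' @param geom A [cell_geometry()].
#' @return A Y x X logical matrix, `TRUE` inside the nucleus.
#' @export
nucleus_mask <- function(geom) {
  ys <- seq_len(geom$image_shape[1]); xs <- seq_len(geom$image_shape[2])
  xm <- matrix(xs, nrow = length(ys), ncol = length(xs), byrow = TRUE)
  ym <- matrix(ys, nrow = length(ys), ncol = length(xs))
  ((xm - geom$nucleus_center[1]) / geom$nucleus_axes[1])^2 +
    ((ym - geom$nucleus_center[2]) / geom$nucleus_axes[2])^2 <= 1
}

#' Optics and camera noise model
#'
#' Gain and noise parameters mapping model fluorescence (arbitrary units)
#' to camera counts in the rendered movies. Transcriptional foci receive a
#' total expected photon count `photons_per_au * T_i(t)` distributed over
#' the z-stack by a Gaussian axial profile and over pixels by a Gaussian
#' lateral PSF; nuclear fills are expected photons per pixel.
#'
#' @param psf_sigma_xy_px Lateral PSF sigma (px).
#' @param psf_sigma_z_um Axial PSF sigma (um).
#' @param photons_per_au Total focus photons per unit transcription rate.
#' @param mcp_nuclear_background_au Diffuse nuclear MCP background
#'   (photons/px).
#' @param yfp_autofluorescence_au Nuclear autofluorescence in the reporter
#'   channel (photons/px).
#' @param yfp_photons_per_au_px Reporter-channel gain (photons/px per a.u.
#'   of protein).
#' @param h2b_fill_photons Nuclear-marker fill (photons/px).
#' @param ambient_photons Extranuclear background (photons/px).
#' @param read_noise_sd Gaussian read noise (counts).
#' @param camera_offset Camera offset (counts).
#' @param bit_depth 8 or 16.
#' @param poisson_noise Disable to render noise-free expectations
#'   (useful together with `read_noise_sd = 0` for ground-truth checks).
#' @return An object of class `optics_noise`.
#' @export
optics_noise <- function(psf_sigma_xy_px = 1.3, psf_sigma_z_um = 1.0,
                         photons_per_au = 12000,
                         mcp_nuclear_background_au = 30,
                         yfp_autofluorescence_au = 20,
                         yfp_photons_per_au_px = 1,
                         h2b_fill_photons = 300,
                         ambient_photons = 2,
                         read_noise_sd = 3, camera_offset = 100,
                         bit_depth = 16, poisson_noise = TRUE) {
  p <- as.list(environment())
  for (nm in setdiff(names(p), c("bit_depth", "poisson_noise")))
    stopifnot_scalar_number(p[[nm]], nm, min = 0)
  if (!bit_depth %in% c(8, 16))
    abort_validation("`bit_depth` must be 8 or 16")
  structure(p, class = "optics_noise")
}

#' Generate a jittered cell population
#'
#' Produces `n_cells` replicate (geometry, parameters) pairs emulating
#' cell-to-cell variability: expression-scale parameters (transcription and
#' translation rates, mRNA and reporter turnover, baseline reporter pools)
#' are multiplied by log-normal factors with unit mean and coefficient of
#' variation `cv`, and integration-site positions are re-sampled per cell.
#' Signaling-timing constants (activation/repressor kinetics, Hill
#' threshold and exponent, repression floors, miR-21 multipliers) are
#' shared across the population, as expected for a clonal line driven by a
#' common pathway.
#'
#' @param base_geom A [cell_geometry()] template.
#' @param base_params A [kinetic_params()] template.
#' @param n_cells Number of replicates.
#' @param cv Coefficient of variation of the jitter (>= 0).
#' @param seed Integer seed; same seed, same population.
#' @return A list of `n_cells` lists with elements `geometry` and `params`.
#' @export
jitter_population <- function(base_geom, base_params, n_cells, cv, seed) {
  if (!is.numeric(cv) || length(cv) != 1L || is.na(cv) || cv < 0)
    abort_validation("`cv` must be a single number >= 0")
  stopifnot_scalar_number(n_cells, "n_cells", min = 1)
  base_params <- as_kinetic_params(base_params)
  jitter_fields <- c("k_tx", "k_tl", "delta_m0", "delta_p0_yfp",
                     "delta_p0_dgfp", "p_basal_yfp", "p_basal_dgfp")
  sdlog <- sqrt(log(1 + cv^2))
  withr::with_seed(as.integer(seed), {
    lapply(seq_len(n_cells), function(i) {
      p <- unclass(base_params)
      if (cv > 0) {
        f <- stats::rlnorm(length(jitter_fields),
                           meanlog = -sdlog^2 / 2, sdlog = sdlog)
        for (k in seq_along(jitter_fields))
          p[[jitter_fields[k]]] <- p[[jitter_fields[k]]] * f[k]
      }
      # dGFP must stay less stable than msfYFP after jitter
      if (p$delta_p0_dgfp <= p$delta_p0_yfp)
        p$delta_p0_dgfp <- p$delta_p0_yfp * 1.5
      g <- if (cv == 0) base_geom else
        cell_geometry(image_shape = base_geom$image_shape,
                      pixel_size_um = base_geom$pixel_size_um,
                      nucleus_center = base_geom$nucleus_center,
                      nucleus_axes = base_geom$nucleus_axes,
                      n_sites = nrow(base_geom$site_positions),
                      min_separation_px = base_geom$min_separation_px,
                      seed = sample.int(.Machine$integer.max, 1))
      list(geometry = g, params = as_kinetic_params(p))
    })
  })
}
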