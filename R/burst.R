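#' Maximum-intensity projection of a z-stack
#'
#' Projects a Z x Y x X slab onto a single plane by taking the pixelwise
#' maximum over z, so that all transcriptional foci are visible in one
#' image regardless of their axial position.
#'
#' @param zstack A Z x Y x X numeric array (Z >= 1), or a Y x X matrix
#'   (returned unchanged).
#' @return A Y x X matrix.
#' @export
max_project <- function(zstack) {
  if (is.matrix(zstack)) return(zstack)
  d <- dim(zstack)
  if (is.null(d) || length(d) != 3L || d[1] < 1L)
    abort_validation("`zstack` must be a Z x Y x X array with Z >= 1")
  out <- zstack[1, , ]
  if (d[1] > 1L)
    for (z in 2:d[1]) out <- pmax(out, zstack[z, , ])
  out
}

# scale-normalized Laplacian-of-Gaussian kernel (sign-flipped so bright
# blobs give positive response)
log_kernel <- function(sigma) {
  half <- ceiling(3 * sigma)
  xs <- -half:half
  g <- exp(-xs^2 / (2 * sigma^2))
  G <- outer(g, g)
  r2 <- outer(xs^2, xs^2, "+")
  k <- -(r2 - 2 * sigma^2) / sigma^4 * G
  k <- k * sigma^2              # scale normalization
  k - mean(k)                   # zero-sum: flat backgrounds give 0 response
}

#' Detect transcriptional foci in a projected image
#'
#' Laplacian-of-Gaussian blob detection restricted to the nucleus.
#' Candidate pixels must exceed `median + snr_threshold * MAD` of the
#' masked LoG response, and candidates closer than `min_separation_px` are
#' merged by non-maximum suppression (strongest kept).
#'
#' @param image Y x X numeric matrix (typically a [max_project()]ed MCP
#'   frame).
#' @param nucleus_mask Y x X logical matrix; detection is restricted to it.
#' @param log_sigma_px LoG scale, matched to the focus radius (px).
#' @param snr_threshold Robust SNR threshold (default 5).
#' @param min_separation_px Minimum separation between detections (px; secondary noise maxima within this radius of a focus are suppressed).
#' @return A data frame with columns `x_px`, `y_px`, `score`, sorted by
#'   decreasing score (0 rows when nothing is detected).
#' @export
detect_foci <- function(image, nucleus_mask, log_sigma_px = 1.3,
                        snr_threshold = 5, min_separation_px = 6) {
  if (!is.matrix(image)) abort_validation("`image` must be a matrix")
  if (!is.logical(nucleus_mask) || !identical(dim(nucleus_mask), dim(image)))
    abort_validation("`nucleus_mask` must be a logical matrix matching `image`")
  if (!any(nucleus_mask)) abort_validation("nucleus mask is empty")

  k <- log_kernel(log_sigma_px)
  resp <- EBImage::filter2(image, k, boundary = "replicate")
  resp <- matrix(as.numeric(resp), nrow(image), ncol(image))

  v <- resp[nucleus_mask]
  scale_v <- stats::mad(v)
  if (scale_v <= 0) scale_v <- stats::sd(v)   # noise-free images
  thr <- stats::median(v) + snr_threshold * scale_v

  # the nuclear rim is a brightness step that rings under the LoG filter;
  # candidates are restricted to the mask eroded by the kernel radius
  inner <- EBImage::erode(nucleus_mask * 1L,
                          EBImage::makeBrush(2L * ceiling(2 * log_sigma_px) +
                                               1L, shape = "disc")) > 0
  cand <- which(inner & resp > thr, arr.ind = TRUE)
  if (nrow(cand) == 0L)
    return(data.frame(x_px = numeric(0), y_px = numeric(0),
                      score = numeric(0)))
  sc <- resp[cand]
  o <- order(sc, decreasing = TRUE)
  cand <- cand[o, , drop = FALSE]; sc <- sc[o]

  keep_x <- numeric(0); keep_y <- numeric(0); keep_s <- numeric(0)
  for (i in seq_len(nrow(cand))) {
    x <- cand[i, 2]; y <- cand[i, 1]
    if (length(keep_x) == 0L ||
        min(sqrt((keep_x - x)^2 + (keep_y - y)^2)) >= min_separation_px) {
      keep_x <- c(keep_x, x); keep_y <- c(keep_y, y); keep_s <- c(keep_s, sc[i])
    }
  }
  data.frame(x_px = keep_x, y_px = keep_y, score = keep_s)
}

#' Fit an axis-aligned 2D Gaussian to a focus
#'
#' Least-squares fit of
#' `f(x, y) = b + A exp(-(x - x0)^2 / (2 sx^2) - (y - y0)^2 / (2 sy^2))`
#' over a square region of interest centred on `center_guess`. The burst
#' intensity is the integrated area under the fitted Gaussian above
#' background, `I = 2 * pi * A * sx * sy`. Initialization uses the ROI
#' maximum and intensity moments; bounds keep the centre inside the ROI
#' and the widths within `sigma_bounds`.
#'
#' @param image Y x X numeric matrix.
#' @param center_guess `c(x, y)` centre in pixels; the ROI must lie fully
#'   inside the image.
#' @param roi_halfwidth_px ROI half-width (default 4, a 9 x 9 window).
#' @param sigma_bounds Width bounds in px (default `c(0.5, roi_halfwidth)`).
#' @param fallback_sigma_px When the free fit runs into the width bounds
#'   (typical for frames with no burst, where a free-width "fit" latches
#'   onto background structure), the fit is retried with both widths fixed
#'   at this PSF-scale value, so weak frames report small intensities
#'   rather than spuriously large ones. Set to `NULL` to disable (the
#'   bound-hitting fit is then reported as not converged).
#' @return An object of class `gaussian_fit`: amplitude, center, sigma,
#'   background, `integrated_intensity` (NA when not converged), residual
#'   norm and a `converged` flag. A fit with amplitude at the lower bound
#'   (e.g. on a flat image) is reported as not converged rather than as a
#'   zero-intensity burst.
#' @examples
#' img <- outer(1:21, 1:21, function(y, x)
#'   10 + 100 * exp(-((x - 11)^2 + (y - 11)^2) / (2 * 1.5^2)))
#' f <- fit_gaussian2d(img, c(11, 11))
#' abs(f$integrated_intensity - 2 * pi * 100 * 1.5^2) < 1e-2
#' @export
fit_gaussian2d <- function(image, center_guess, roi_halfwidth_px = 4,
                           sigma_bounds = NULL, fallback_sigma_px = 1.3) {
  hw <- as.integer(roi_halfwidth_px)
  if (is.null(sigma_bounds)) sigma_bounds <- c(0.5, hw)
  cx <- round(center_guess[1]); cy <- round(center_guess[2])
  ny <- nrow(image); nx <- ncol(image)
  if (cx - hw < 1 || cx + hw > nx || cy - hw < 1 || cy + hw > ny)
    abort_validation("ROI around (%g, %g) extends outside the image",
                     center_guess[1], center_guess[2])
  xs <- (cx - hw):(cx + hw); ys <- (cy - hw):(cy + hw)
  roi <- image[ys, xs]
  xm <- matrix(xs, length(ys), length(xs), byrow = TRUE)
  ym <- matrix(ys, length(ys), length(xs))

  b0 <- stats::median(c(roi[1, ], roi[nrow(roi), ], roi[, 1], roi[, ncol(roi)]))
  a0 <- max(roi) - b0
  not_converged <- function(resid = NA_real_) {
    structure(list(amplitude = NA_real_, center = c(NA_real_, NA_real_),
                   sigma = c(NA_real_, NA_real_), background = b0,
                   integrated_intensity = NA_real_,
                   residual_norm = resid, converged = FALSE),
              class = "gaussian_fit")
  }
  if (!is.finite(a0) || a0 <= 0) return(not_converged())

  w <- pmax(roi - b0, 0)
  sw <- sum(w)
  x0 <- if (sw > 0) sum(w * xm) / sw else cx
  y0 <- if (sw > 0) sum(w * ym) / sw else cy
  sx0 <- if (sw > 0) sqrt(max(sum(w * (xm - x0)^2) / sw, 0.25)) else 1.5
  sy0 <- if (sw > 0) sqrt(max(sum(w * (ym - y0)^2) / sw, 0.25)) else 1.5
  clamp <- function(v, lo, hi) min(max(v, lo), hi)
  start <- c(b = b0, A = a0,
             x0 = clamp(x0, min(xs), max(xs)),
             y0 = clamp(y0, min(ys), max(ys)),
             sx = clamp(sx0, sigma_bounds[1], sigma_bounds[2]),
             sy = clamp(sy0, sigma_bounds[1], sigma_bounds[2]))
  lower <- c(-Inf, 0, min(xs), min(ys), sigma_bounds[1], sigma_bounds[1])
  upper <- c(Inf, Inf, max(xs), max(ys), sigma_bounds[2], sigma_bounds[2])

  resid_fun <- function(p) {
    mu <- p[1] + p[2] * exp(-(xm - p[3])^2 / (2 * p[5]^2) -
                              (ym - p[4])^2 / (2 * p[6]^2))
    as.numeric(mu - roi)
  }
  fit <- try(minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                                fn = resid_fun,
                                control = minpack.lm::nls.lm.control(
                                  maxiter = 200)),
             silent = TRUE)
  if (inherits(fit, "try-error")) return(not_converged())
  p <- fit$par
  resid <- sqrt(sum(fit$fvec^2))
  amp_ok <- function(par) par[2] > 1e-6 * max(abs(a0), 1)
  # free widths running into their bounds mean the "focus" is background
  # structure; retry with the widths pinned at the PSF scale
  tol_s <- 1e-3
  sig_interior <- all(p[5:6] > sigma_bounds[1] + tol_s) &&
    all(p[5:6] < sigma_bounds[2] - tol_s)
  if (fit$info %in% 1:4 && amp_ok(p) && !sig_interior &&
      !is.null(fallback_sigma_px)) {
    resid_fixed <- function(q) {
      mu <- q[1] + q[2] * exp(-(xm - q[3])^2 / (2 * fallback_sigma_px^2) -
                                (ym - q[4])^2 / (2 * fallback_sigma_px^2))
      as.numeric(mu - roi)
    }
    fit2 <- try(minpack.lm::nls.lm(par = start[1:4],
                                   lower = lower[1:4], upper = upper[1:4],
                                   fn = resid_fixed,
                                   control = minpack.lm::nls.lm.control(
                                     maxiter = 200)),
                silent = TRUE)
    if (!inherits(fit2, "try-error") && fit2$info %in% 1:4) {
      # a pinned-width fit with vanishing amplitude is a genuine "no burst
      # right now" measurement (~0), not a failure
      q <- fit2$par
      return(structure(list(amplitude = unname(q[2]),
                            center = unname(c(q[3], q[4])),
                            sigma = c(fallback_sigma_px, fallback_sigma_px),
                            background = unname(q[1]),
                            integrated_intensity =
                              unname(2 * pi * q[2] * fallback_sigma_px^2),
                            residual_norm = sqrt(sum(fit2$fvec^2)),
                            converged = TRUE),
                       class = "gaussian_fit"))
    }
    return(not_converged(resid))
  }
  ok <- fit$info %in% 1:4 && amp_ok(p) && sig_interior
  if (!ok) return(not_converged(resid))
  structure(list(amplitude = unname(p[2]),
                 center = unname(c(p[3], p[4])),
                 sigma = unname(c(p[5], p[6])),
                 background = unname(p[1]),
                 integrated_intensity = unname(2 * pi * p[2] * p[5] * p[6]),
                 residual_norm = resid, converged = TRUE),
            class = "gaussian_fit")
}

#' Link per-frame detections into stationary focus tracks
#'
#' Greedy nearest-neighbour linking for (nearly) stationary transcription
#' sites: a detection is assigned to the track whose last position is
#' within `max_disp_px`, allowing gaps of up to `max_gap_frames` missed
#' frames; unmatched detections open new tracks, and tracks observed in
#' fewer than `min_frames` frames are discarded. Each track's mean
#' position is the reference for re-fitting missed frames in
#' [burst_traces()].
#'
#' @param detections A list (one element per frame) of data frames as
#'   returned by [detect_foci()].
#' @param max_disp_px Maximum frame-to-frame displacement (default 3).
#' @param max_gap_frames Maximum gap to bridge (default 3).
#' @param min_frames Minimum frames a track must be present in (default 8; a transcribing site is visible for tens of frames).
#' @return A list of `focus_track` objects (`site_id`, per-frame `frame`,
#'   `x_px`, `y_px`, `score`, `mean_position`, `frames_present`).
#' @export
track_foci <- function(detections, max_disp_px = 3, max_gap_frames = 3,
                       min_frames = 8) {
  tracks <- list()   # each: list(frames, x, y, score, last_frame)
  for (f in seq_along(detections)) {
    det <- detections[[f]]
    if (is.null(det) || nrow(det) == 0L) next
    open <- which(vapply(tracks, function(tr)
      f - tr$last_frame <= max_gap_frames + 1L, logical(1)))
    used <- logical(length(open))
    for (j in seq_len(nrow(det))) {
      best <- NA_integer_; bestd <- Inf
      for (oi in seq_along(open)) {
        if (used[oi]) next
        tr <- tracks[[open[oi]]]
        d <- sqrt((mean(tr$x) - det$x_px[j])^2 + (mean(tr$y) - det$y_px[j])^2)
        if (d <= max_disp_px && d < bestd) { best <- oi; bestd <- d }
      }
      if (!is.na(best)) {
        used[best] <- TRUE
        ti <- open[best]
        tracks[[ti]]$frames <- c(tracks[[ti]]$frames, f)
        tracks[[ti]]$x <- c(tracks[[ti]]$x, det$x_px[j])
        tracks[[ti]]$y <- c(tracks[[ti]]$y, det$y_px[j])
        tracks[[ti]]$score <- c(tracks[[ti]]$score, det$score[j])
        tracks[[ti]]$last_frame <- f
      } else {
        tracks[[length(tracks) + 1L]] <-
          list(frames = f, x = det$x_px[j], y = det$y_px[j],
               score = det$score[j], last_frame = f)
      }
    }
  }
  tracks <- Filter(function(tr) length(tr$frames) >= min_frames, tracks)
  lapply(seq_along(tracks), function(i) {
    tr <- tracks[[i]]
    structure(list(site_id = i, frame = tr$frames,
                   x_px = tr$x, y_px = tr$y, score = tr$score,
                   mean_position = c(mean(tr$x), mean(tr$y)),
                   frames_present = length(tr$frames)),
              class = "focus_track")
  })
}

#' Detect and track foci across a whole movie
#'
#' Convenience wrapper: max-projects the MCP channel of every frame, runs
#' [detect_foci()] per frame, and links the detections with [track_foci()].
#'
#' @param movie A `movie_stack`.
#' @param mask Nucleus mask; defaults to the attached ground-truth
#'   geometry's mask.
#' @param log_sigma_px,snr_threshold,min_separation_px See [detect_foci()].
#' @param max_disp_px,max_gap_frames,min_frames See [track_foci()].
#' @return A list with `tracks` (list of `focus_track`) and `detections`
#'   (per-frame data frames).
#' @export
detect_and_track <- function(movie, mask = NULL, log_sigma_px = 1.3,
                             snr_threshold = 5, min_separation_px = 6,
                             max_disp_px = 3, max_gap_frames = 3,
                             min_frames = 8) {
  mask <- mask %||% movie_mask(movie)
  n_t <- dim(movie$data)[1]
  detections <- lapply(seq_len(n_t), function(t)
    detect_foci(max_project(movie_slab(movie, t, "MCP")), mask,
                log_sigma_px = log_sigma_px, snr_threshold = snr_threshold,
                min_separation_px = min_separation_px))
  list(tracks = track_foci(detections, max_disp_px = max_disp_px,
                           max_gap_frames = max_gap_frames,
                           min_frames = min_frames),
       detections = detections)
}

movie_mask <- function(movie) {
  g <- movie$ground_truth$geometry
  if (is.null(g))
    abort_validation("no nucleus mask available: supply `mask` or attach ground truth")
  if (inherits(g, "cell_geometry")) return(nucleus_mask(g))
  # geometry reconstructed from a sidecar
  geom <- list(image_shape = g$image_shape,
               nucleus_center = g$nucleus_center,
               nucleus_axes = g$nucleus_axes)
  ys <- seq_len(geom$image_shape[1]); xs <- seq_len(geom$image_shape[2])
  xm <- matrix(xs, length(ys), length(xs), byrow = TRUE)
  ym <- matrix(ys, length(ys), length(xs))
  ((xm - geom$nucleus_center[1]) / geom$nucleus_axes[1])^2 +
    ((ym - geom$nucleus_center[2]) / geom$nucleus_axes[2])^2 <= 1
}

#' Quantify burst intensity traces along tracks
#'
#' For every frame, max-projects the movie's MCP z-slab and fits a 2D
#' Gaussian ([fit_gaussian2d()]) at each track's mean position, recording
#' the integrated intensity. Fits are attempted on every frame (also where
#' the focus was not detected), so traces cover the full timecourse;
#' failed fits are recorded as missing values, never as zeros.
#'
#' @param movie A `movie_stack` containing an MCP channel.
#' @param tracks Tracks from [track_foci()] / [detect_and_track()].
#' @param roi_halfwidth_px ROI half-width for the fits.
#' @return A list with `traces` (per-track [intensity_trace()]) and `fits`
#'   (long data frame: track_id, frame, time_min, x_px, y_px, amplitude,
#'   sigma_x, sigma_y, background, integrated_intensity, converged).
#' @export
burst_traces <- function(movie, tracks, roi_halfwidth_px = 4) {
  if (!inherits(movie, "movie_stack"))
    abort_validation("`movie` must be a movie_stack")
  if (!"MCP" %in% movie$channel_roles)
    abort_validation("movie has no MCP channel")
  n_t <- dim(movie$data)[1]
  rows <- vector("list", n_t * length(tracks))
  k <- 0L
  for (t in seq_len(n_t)) {
    img <- max_project(movie_slab(movie, t, "MCP"))
    for (tr in tracks) {
      k <- k + 1L
      fit <- tryCatch(
        fit_gaussian2d(img, tr$mean_position, roi_halfwidth_px),
        synieg_validation = function(e) NULL)
      rows[[k]] <- data.frame(
        track_id = tr$site_id, frame = t,
        time_min = movie$time_min[t],
        x_px = if (!is.null(fit) && fit$converged) fit$center[1] else NA_real_,
        y_px = if (!is.null(fit) && fit$converged) fit$center[2] else NA_real_,
        amplitude = if (is.null(fit)) NA_real_ else fit$amplitude,
        sigma_x = if (is.null(fit)) NA_real_ else fit$sigma[1],
        sigma_y = if (is.null(fit)) NA_real_ else fit$sigma[2],
        background = if (is.null(fit)) NA_real_ else fit$background,
        integrated_intensity =
          if (is.null(fit)) NA_real_ else fit$integrated_intensity,
        converged = !is.null(fit) && fit$converged)
    }
  }
  fits <- do.call(rbind, rows)
  traces <- lapply(tracks, function(tr) {
    sub <- fits[fits$track_id == tr$site_id, ]
    sub <- sub[order(sub$frame), ]
    intensity_trace(sub$time_min, sub$integrated_intensity,
                    label = paste0("site", tr$site_id),
                    stim_onset_min = movie$stim_onset_min)
  })
  names(traces) <- vapply(tracks, function(tr)
    paste0("site", tr$site_id), character(1))
  list(traces = traces, fits = fits)
}

#' Write burst-trace fits to CSV
#' @param bursts Result of [burst_traces()].
#' @param path Output CSV.
#' @return `path`, invisibly.
#' @export
write_burst_csv <- function(bursts, path) {
  utils::write.csv(bursts$fits, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.gaussian_fit <- function(x, ...) {
  if (x$converged)
    cat(sprintf("<gaussian_fit> A=%.3g at (%.2f, %.2f), sigma=(%.2f, %.2f), b=%.3g, I=%.4g\n",
                x$amplitude, x$center[1], x$center[2], x$sigma[1], x$sigma[2],
                x$background, x$integrated_intensity))
  else cat("<gaussian_fit> not converged\n")
  invisible(x)
}

#' @export
print.focus_track <- function(x, ...) {
  cat(sprintf("<focus_track> site %d: %d frames, mean position (%.1f, %.1f)\n",
              x$site_id, x$frames_present, x$mean_position[1],
              x$mean_position[2]))
  invisible(x)
}
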