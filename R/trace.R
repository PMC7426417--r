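#' Construct an intensity trace
#'
#' A time series of fluorescence values for one focus or one nucleus.
#' Missing values are allowed (failed fits); the baseline is the mean of
#' the first two timepoints, which for the package's stimulus presets are
#' acquired before stimulation.
#'
#' @param times Time in minutes, strictly increasing.
#' @param values Intensities (a.u.); NA allowed.
#' @param label Identifier (cell/track/condition).
#' @param stim_onset_min Time of stimulation on the `times` axis; kinetic
#'   metrics are reported relative to it.
#' @return An object of class `intensity_trace`.
#' @export
intensity_trace <- function(times, values, label = "",
                            stim_onset_min = 0) {
  if (length(times) != length(values))
    abort_validation("`times` and `values` must have the same length")
  if (any(diff(times) <= 0))
    abort_validation("`times` must be strictly increasing")
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 label = label, stim_onset_min = stim_onset_min),
            class = "intensity_trace")
}

#' Baseline of a trace (mean of the first two timepoints)
#' @param trace An [intensity_trace()].
#' @return The baseline value; errors if either of the first two values is
#'   missing.
#' @export
trace_baseline <- function(trace) {
  if (length(trace$values) < 2L)
    abort_validation("trace needs at least 2 timepoints for a baseline")
  v <- trace$values[1:2]
  if (anyNA(v))
    abort_validation("baseline undefined: first two timepoints must be present")
  mean(v)
}

#' Protein trace of a simulated trajectory
#' @param traj A trajectory from [simulate_circuit()].
#' @return The protein timecourse as an [intensity_trace()].
#' @export
protein_trace <- function(traj) {
  intensity_trace(traj$time_min, traj$protein, label = "protein",
                  stim_onset_min = attr(traj, "stim_onset_min") %||% 0)
}

#' Mean per-site transcription trace of a trajectory
#' @param traj A trajectory.
#' @return Mean transcription rate across sites as an [intensity_trace()].
#' @export
transcription_trace <- function(traj) {
  intensity_trace(traj$time_min, rowMeans(transcription_rates(traj)),
                  label = "transcription",
                  stim_onset_min = attr(traj, "stim_onset_min") %||% 0)
}

#' Nuclear mean-intensity trace from a movie
#'
#' Per frame, the mean of the masked pixels of the central z-slice of the
#' requested channel -- the live-cell measurement used for diffuse reporter
#' quantification (the central slice is the best-focus proxy; no
#' projection is applied for nuclear means).
#'
#' @param movie A `movie_stack`.
#' @param channel Channel role (default `"YFP"`).
#' @param mask Logical Y x X mask; defaults to the attached geometry's
#'   nucleus mask.
#' @return An [intensity_trace()].
#' @export
nuclear_mean_trace <- function(movie, channel = "YFP", mask = NULL) {
  ci <- channel_index(movie, channel)
  mask <- mask %||% movie_mask(movie)
  if (!any(mask)) abort_validation("mask is empty")
  n_t <- dim(movie$data)[1]
  zc <- (dim(movie$data)[2] + 1L) %/% 2L
  vals <- vapply(seq_len(n_t), function(t) {
    sl <- movie$data[t, zc, ci, , ]
    mean(sl[mask])
  }, numeric(1))
  intensity_trace(movie$time_min, vals, label = paste0("nuclear_", channel),
                  stim_onset_min = movie$stim_onset_min)
}

#' Baseline-anchored area under the curve
#'
#' The summary statistic used for reporter induction:
#' `AUC = sum_t (intensity(t) - initial)` where `initial` is the mean of
#' the first two timepoints. The plain sum runs over all frames (including
#' the two baseline frames); missing values are skipped and counted.
#' Units are a.u. x frames. The AUC of a constant trace is zero and the
#' statistic is invariant under adding a constant to the whole trace.
#'
#' @param trace An [intensity_trace()] with at least 2 timepoints; the
#'   first two must be non-missing.
#' @return An object of class `auc_result`: `auc`, `baseline`,
#'   `n_timepoints`, `n_missing`, `t_final`.
#' @examples
#' compute_auc(intensity_trace(1:4, c(1, 1, 2, 3)))$auc  # 3
#' @export
compute_auc <- function(trace) {
  if (!inherits(trace, "intensity_trace"))
    abort_validation("`trace` must be an intensity_trace")
  if (length(trace$values) < 2L)
    abort_validation("AUC needs at least 2 timepoints")
  initial <- trace_baseline(trace)
  dev <- trace$values - initial
  structure(list(auc = sum(dev, na.rm = TRUE),
                 baseline = initial,
                 n_timepoints = length(trace$values),
                 n_missing = sum(is.na(trace$values)),
                 t_final = trace$times[length(trace$times)]),
            class = "auc_result")
}

#' Fold-change of a trace over its baseline
#'
#' `fold = value(t_final) / baseline` by default (`method = "final"`), or
#' the maximum value over baseline (`method = "max"`). The percent
#' increase is `100 * (fold - 1)`; decreases give negative percentages
#' (no clipping).
#'
#' @param trace An [intensity_trace()] with positive baseline.
#' @param method `"final"` (default) or `"max"`.
#' @return A list with `fold` and `percent`.
#' @export
fold_change <- function(trace, method = c("final", "max")) {
  method <- match.arg(method)
  b <- trace_baseline(trace)
  if (b <= 0)
    abort_validation("baseline must be > 0 for a fold-change; consider offsetting the trace")
  v <- trace$values
  final <- if (method == "final") {
    vv <- v[!is.na(v)]
    if (!length(vv)) abort_validation("trace has no non-missing values")
    vv[length(vv)]
  } else max(v, na.rm = TRUE)
  fold <- final / b
  list(fold = fold, percent = 100 * (fold - 1))
}

#' Kinetic timing metrics of a stimulus response
#'
#' `time_to_peak_min` is the time (relative to stimulation) at which the
#' trace is maximal; `adaptation_time_min` is the first post-peak time at
#' which the trace has returned to within `noise_sd` of its baseline
#' (`NA` if it never does). Only the post-stimulation part of the trace is
#' considered for the peak. The baseline reference uses the mean of all
#' pre-stimulus frames when the trace has them (a more stable estimate
#' than the two-frame AUC anchor), falling back to the mean of the first
#' two timepoints otherwise.
#'
#' @param trace An [intensity_trace()] covering the stimulus epoch.
#' @param noise_sd Noise tolerance around the baseline (same units as the
#'   trace). For quantified movies, estimate it from the pre-stimulus
#'   frames (see [prestim_noise_sd()]).
#' @return A list with `time_to_peak_min` and `adaptation_time_min`.
#' @export
kinetic_metrics <- function(trace, noise_sd = 0) {
  if (all(is.na(trace$values)))
    abort_validation("trace is all-missing")
  onset <- trace$stim_onset_min %||% 0
  pre <- trace$values[trace$times < onset]
  pre <- pre[!is.na(pre)]
  base <- if (length(pre) >= 2L) mean(pre) else trace_baseline(trace)
  post <- which(trace$times >= onset & !is.na(trace$values))
  if (!length(post)) abort_validation("trace does not cover the stimulus epoch")
  pk <- post[which.max(trace$values[post])]
  t_peak <- trace$times[pk] - onset
  after <- post[post > pk]
  reached <- after[trace$values[after] <= base + noise_sd]
  list(time_to_peak_min = t_peak,
       adaptation_time_min =
         if (length(reached)) trace$times[reached[1]] - onset else NA_real_)
}

#' Noise SD of the pre-stimulus frames of a trace
#' @param trace An [intensity_trace()] with a stimulus onset > 0.
#' @return Standard deviation of the pre-stimulus values.
#' @export
prestim_noise_sd <- function(trace) {
  pre <- trace$values[trace$times < (trace$stim_onset_min %||% 0)]
  pre <- pre[!is.na(pre)]
  if (length(pre) < 2L)
    abort_validation("need >= 2 pre-stimulus frames to estimate noise")
  stats::sd(pre)
}

#' Pooled pre-stimulus noise SD of a set of traces
#'
#' Estimates the noise level of the *mean* trace of `traces` from the
#' pre-stimulus frames, pooling the per-trace variances across traces:
#' `sqrt(mean(var_i) / n_traces)`. With several traces this is a much more
#' stable estimate of the mean trace's frame-to-frame noise than the SD of
#' its few pre-stimulus values.
#'
#' @param traces List of [intensity_trace()] on a common grid with
#'   pre-stimulus frames.
#' @return The pooled noise SD of the mean trace.
#' @export
pooled_prestim_noise_sd <- function(traces) {
  check_common_grid(traces)
  vars <- vapply(traces, function(tr) {
    pre <- tr$values[tr$times < (tr$stim_onset_min %||% 0)]
    pre <- pre[!is.na(pre)]
    if (length(pre) < 2L) NA_real_ else stats::var(pre)
  }, numeric(1))
  vars <- vars[!is.na(vars)]
  if (!length(vars))
    abort_validation("need >= 2 pre-stimulus frames in at least one trace")
  sqrt(mean(vars) / length(traces))
}

#' Average several traces on a common grid
#' @param traces List of [intensity_trace()] on identical time grids.
#' @return The mean [intensity_trace()] (missing-aware).
#' @export
mean_trace <- function(traces) {
  check_common_grid(traces)
  vals <- rowMeans(do.call(cbind, lapply(traces, `[[`, "values")),
                   na.rm = TRUE)
  intensity_trace(traces[[1]]$times, vals, label = "mean",
                  stim_onset_min = traces[[1]]$stim_onset_min)
}

check_common_grid <- function(traces) {
  if (!length(traces)) abort_validation("no traces supplied")
  t0 <- traces[[1]]$times
  for (tr in traces)
    if (!isTRUE(all.equal(tr$times, t0)))
      abort_validation("traces are on different time grids; resample first")
  invisible(TRUE)
}

#' Summarize traces by condition
#'
#' Computes the per-trace AUC and fold-change and aggregates them per
#' condition: mean, SD, SEM (`SD/sqrt(n)`) and n.
#'
#' @param traces List of [intensity_trace()].
#' @param condition Character vector of condition labels, one per trace
#'   (default: all `"all"`).
#' @return A list with `per_trace` (data frame: label, condition, auc,
#'   fold, percent) and `summary` (data frame: condition, n, mean_auc,
#'   sd_auc, sem_auc, mean_fold, sd_fold, sem_fold).
#' @export
aggregate_traces <- function(traces, condition = NULL) {
  if (!length(traces)) abort_validation("no traces supplied")
  condition <- condition %||% rep("all", length(traces))
  if (length(condition) != length(traces))
    abort_validation("`condition` must have one label per trace")
  per <- do.call(rbind, lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    # traces whose baseline frames are missing (e.g. failed fits on the
    # first frames) contribute NA rather than aborting the aggregation
    fc <- tryCatch(fold_change(tr), synieg_validation = function(e)
      list(fold = NA_real_, percent = NA_real_))
    auc <- tryCatch(compute_auc(tr)$auc,
                    synieg_validation = function(e) NA_real_)
    data.frame(label = tr$label, condition = condition[i],
               auc = auc, fold = fc$fold, percent = fc$percent)
  }))
  agg <- do.call(rbind, lapply(split(per, per$condition), function(d) {
    n <- sum(!is.na(d$auc))
    data.frame(condition = d$condition[1], n = n,
               mean_auc = mean(d$auc, na.rm = TRUE),
               sd_auc = stats::sd(d$auc[!is.na(d$auc)]),
               sem_auc = stats::sd(d$auc[!is.na(d$auc)]) / sqrt(max(n, 1)),
               mean_fold = mean(d$fold, na.rm = TRUE),
               sd_fold = stats::sd(d$fold[!is.na(d$fold)]),
               sem_fold = stats::sd(d$fold[!is.na(d$fold)]) / sqrt(max(n, 1)))
  }))
  rownames(agg) <- NULL
  list(per_trace = per, summary = agg)
}

#' Write / read traces as long-format CSV
#'
#' Columns: `cell_id`, `condition`, `time_min`, `value`; the stimulus
#' onset is stored in a header comment.
#'
#' @param traces List of [intensity_trace()].
#' @param condition Condition labels (recycled).
#' @param path CSV path.
#' @return `path` invisibly (writer); a list of traces with a `condition`
#'   attribute (reader).
#' @export
write_traces_csv <- function(traces, path, condition = NULL) {
  condition <- condition %||% rep("all", length(traces))
  condition <- rep_len(condition, length(traces))
  df <- do.call(rbind, lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    data.frame(cell_id = if (nzchar(tr$label)) tr$label else paste0("cell", i),
               condition = condition[i],
               time_min = tr$times, value = tr$values)
  }))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# stim_onset_min: %g",
                     traces[[1]]$stim_onset_min %||% 0), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces_csv
#' @export
read_traces_csv <- function(path) {
  hdr <- readLines(path, n = 1L)
  onset <- 0
  if (startsWith(hdr, "#"))
    onset <- as.numeric(regmatches(hdr, regexpr("[0-9.]+", hdr)))
  df <- utils::read.csv(path, comment.char = "#")
  sp <- split(df, list(df$cell_id, df$condition), drop = TRUE)
  traces <- lapply(sp, function(d)
    intensity_trace(d$time_min, d$value, label = d$cell_id[1],
                    stim_onset_min = onset))
  attr(traces, "condition") <- vapply(sp, function(d)
    as.character(d$condition[1]), character(1))
  traces
}

#' @export
print.intensity_trace <- function(x, ...) {
  cat(sprintf("<intensity_trace> %s: %d timepoints, %g--%g min\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' @export
print.auc_result <- function(x, ...) {
  cat(sprintf("<auc_result> AUC %.4g (baseline %.4g, %d frames%s)\n",
              x$auc, x$baseline, x$n_timepoints,
              if (x$n_missing) sprintf(", %d missing", x$n_missing) else ""))
  invisible(x)
}
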