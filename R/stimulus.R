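#' Define an experimental stimulation program
#'
#' A stimulus program describes one imaging experiment: how long the cell is
#' followed, the acquisition interval, and the schedule of serum, blue light
#' (OptoSOS), doxorubicin, cycloheximide and MEK-inhibitor treatments.
#' Programs are converted to normalized pathway input signals by
#' [make_stimulus()].
#'
#' Times are minutes from the start of acquisition. Serum and doxorubicin are
#' added at `drug_addition_time_min`; light is delivered during
#' `light_windows`. The presets used throughout the package (see
#' [stimulus_preset()]) include a 10-minute pre-stimulus lead-in so that
#' baseline frames exist for anchoring AUC and fold-change statistics.
#'
#' @param duration_min Total acquisition time (minutes, > 0).
#' @param dt_min Frame interval (minutes, > 0).
#' @param serum_fraction Serum volume fraction: 0 (starved), 0.01 or 0.10.
#' @param light_windows List of `c(start, end)` illumination intervals in
#'   minutes; must be ordered, non-overlapping and within
#'   `[0, duration_min]`. Light is on during `[start, end)`.
#' @param doxorubicin_nM Doxorubicin concentration (0 or 860 nM in the
#'   experiments emulated here; any value >= 0 is accepted, only its
#'   presence matters).
#' @param cycloheximide Logical; protein-synthesis inhibition.
#' @param meki_time_min Time of MEK-inhibitor addition (minutes), or `NULL`.
#' @param drug_addition_time_min Time at which serum/doxorubicin are added
#'   (minutes, default 0).
#' @return An object of class `stimulus_program`.
#' @seealso [stimulus_preset()], [make_stimulus()]
#' @examples
#' stimulus_program(180, 2, serum_fraction = 0.10)
#' stimulus_program(190, 2, light_windows = list(c(10, 30)))
#' @export
stimulus_program <- function(duration_min, dt_min = 2,
                             serum_fraction = 0,
                             light_windows = NULL,
                             doxorubicin_nM = 0,
                             cycloheximide = FALSE,
                             meki_time_min = NULL,
                             drug_addition_time_min = 0) {
  stopifnot_scalar_number(duration_min, "duration_min", min = 0)
  if (duration_min <= 0) abort_validation("`duration_min` must be > 0")
  stopifnot_scalar_number(dt_min, "dt_min", min = 0)
  if (dt_min <= 0) abort_validation("`dt_min` must be > 0")
  stopifnot_scalar_number(serum_fraction, "serum_fraction", min = 0)
  stopifnot_scalar_number(doxorubicin_nM, "doxorubicin_nM", min = 0)
  stopifnot_scalar_number(drug_addition_time_min, "drug_addition_time_min",
                          min = 0)
  stopifnot_scalar_number(meki_time_min, "meki_time_min", min = 0,
                          allow_null = TRUE)
  if (!is.logical(cycloheximide) || length(cycloheximide) != 1L)
    abort_validation("`cycloheximide` must be TRUE or FALSE")

  if (!is.null(light_windows)) {
    if (!is.list(light_windows))
      light_windows <- list(light_windows)
    win <- do.call(rbind, lapply(light_windows, function(w) {
      if (!is.numeric(w) || length(w) != 2L)
        abort_validation("each light window must be c(start, end)")
      w
    }))
    if (any(win < 0) || any(win > duration_min))
      abort_validation("light windows must lie within [0, duration_min]")
    if (any(win[, 2] <= win[, 1]))
      abort_validation("light windows must have end > start")
    if (nrow(win) > 1L) {
      o <- order(win[, 1])
      win <- win[o, , drop = FALSE]
      if (any(win[-1, 1] < win[-nrow(win), 2]))
        abort_validation("light windows must not overlap")
    }
  } else {
    win <- matrix(numeric(0), ncol = 2)
  }

  structure(list(duration_min = duration_min,
                 dt_min = dt_min,
                 serum_fraction = serum_fraction,
                 light_windows = win,
                 doxorubicin_nM = doxorubicin_nM,
                 cycloheximide = isTRUE(cycloheximide),
                 meki_time_min = meki_time_min,
                 drug_addition_time_min = drug_addition_time_min),
            class = "stimulus_program")
}

#' Named stimulus presets
#'
#' The stimulation protocols used in the experiments this package emulates.
#' All presets acquire every 2 minutes with a 10-minute pre-stimulus
#' (starvation) lead-in followed by 180 minutes of follow-up:
#'
#' * `starve`: no stimulus (mock addition at 10 min).
#' * `serum10` / `serum1`: 10% or 1% serum added at 10 min.
#' * `transient20`: a 20-min pulse of blue light (10--30 min).
#' * `sustained`: continuous illumination from 10 min to the end.
#' * `sustained90`: a 90-min illumination window (10--100 min).
#' * `dox`: doxorubicin (860 nM) added at 10 min.
#' * `serum1_dox`: 1% serum plus doxorubicin, the AND-gate co-stimulation.
#'
#' @param name Preset name (see above).
#' @param cycloheximide,meki_time_min Optional treatment modifiers applied on
#'   top of the preset.
#' @return A [stimulus_program()].
#' @export
stimulus_preset <- function(name, cycloheximide = FALSE,
                            meki_time_min = NULL) {
  lead <- 10; dur <- lead + 180
  p <- switch(match_enum(name, names(stimulus_preset_names()), "name"),
    starve      = stimulus_program(dur, 2, drug_addition_time_min = lead),
    serum10     = stimulus_program(dur, 2, serum_fraction = 0.10,
                                   drug_addition_time_min = lead),
    serum1      = stimulus_program(dur, 2, serum_fraction = 0.01,
                                   drug_addition_time_min = lead),
    transient20 = stimulus_program(dur, 2,
                                   light_windows = list(c(lead, lead + 20)),
                                   drug_addition_time_min = lead),
    sustained   = stimulus_program(dur, 2,
                                   light_windows = list(c(lead, dur)),
                                   drug_addition_time_min = lead),
    sustained90 = stimulus_program(dur, 2,
                                   light_windows = list(c(lead, lead + 90)),
                                   drug_addition_time_min = lead),
    dox         = stimulus_program(dur, 2, doxorubicin_nM = 860,
                                   drug_addition_time_min = lead),
    serum1_dox  = stimulus_program(dur, 2, serum_fraction = 0.01,
                                   doxorubicin_nM = 860,
                                   drug_addition_time_min = lead))
  p$cycloheximide <- isTRUE(cycloheximide)
  if (!is.null(meki_time_min)) {
    stopifnot_scalar_number(meki_time_min, "meki_time_min", min = 0)
    p$meki_time_min <- meki_time_min
  }
  p
}

stimulus_preset_names <- function() {
  c(starve = "no stimulus",
    serum10 = "10% serum at 10 min",
    serum1 = "1% serum at 10 min",
    transient20 = "20-min light pulse",
    sustained = "continuous light",
    sustained90 = "90-min light window",
    dox = "doxorubicin 860 nM at 10 min",
    serum1_dox = "1% serum + doxorubicin at 10 min")
}

#' Convert a stimulus program to pathway input signals
#'
#' Maps an experimental schedule onto the three normalized inputs seen by a
#' SynIEG circuit: Erk activity `E(t)` (1 while serum is present or a light
#' window is active, 0 otherwise, and forced to 0 from the MEK-inhibitor
#' addition time onward), a DNA-damage signal
#' `D(t) = 1 - exp(-k_D (t - t_add))` after doxorubicin addition, and a
#' protein-synthesis indicator `S(t)` (0 under cycloheximide).
#'
#' @param program A [stimulus_program()].
#' @param params A [kinetic_params()] object; only `k_D` (damage rise rate)
#'   is used here.
#' @return An object of class `pathway_signals`: a list with `time_min`,
#'   `erk`, `damage`, `synthesis` (all on the program's uniform grid),
#'   `stim_onset_min` (time of the first stimulus event, used to express
#'   kinetic metrics relative to stimulation) and `dt_min`.
#' @examples
#' sig <- make_stimulus(stimulus_preset("serum10"))
#' all(sig$erk[sig$time_min >= 10] == 1)
#' @export
make_stimulus <- function(program, params = default_kinetic_params()) {
  if (!inherits(program, "stimulus_program"))
    abort_validation("`program` must be a stimulus_program")
  params <- as_kinetic_params(params)
  tg <- seq(0, program$duration_min, by = program$dt_min)

  erk <- numeric(length(tg))
  if (program$serum_fraction > 0)
    erk[tg >= program$drug_addition_time_min] <- 1
  if (nrow(program$light_windows)) {
    for (i in seq_len(nrow(program$light_windows))) {
      w <- program$light_windows[i, ]
      erk[tg >= w[1] & tg < w[2]] <- 1
    }
  }
  if (!is.null(program$meki_time_min))
    erk[tg >= program$meki_time_min] <- 0

  damage <- numeric(length(tg))
  if (program$doxorubicin_nM > 0) {
    t0 <- program$drug_addition_time_min
    idx <- tg >= t0
    damage[idx] <- 1 - exp(-params$k_D * (tg[idx] - t0))
  }

  synthesis <- rep(if (program$cycloheximide) 0 else 1, length(tg))

  onset <- c(
    if (program$serum_fraction > 0 || program$doxorubicin_nM > 0)
      program$drug_addition_time_min,
    if (nrow(program$light_windows)) program$light_windows[1, 1])
  onset <- if (length(onset)) min(onset) else program$drug_addition_time_min

  structure(list(time_min = tg, erk = erk, damage = damage,
                 synthesis = synthesis,
                 stim_onset_min = onset,
                 dt_min = program$dt_min,
                 program = program),
            class = "pathway_signals")
}

#' @export
print.stimulus_program <- function(x, ...) {
  cat("<stimulus_program> ", x$duration_min, " min, dt ", x$dt_min, " min\n",
      sep = "")
  if (x$serum_fraction > 0)
    cat("  serum ", 100 * x$serum_fraction, "% at ",
        x$drug_addition_time_min, " min\n", sep = "")
  if (nrow(x$light_windows))
    cat("  light:", paste(apply(x$light_windows, 1, function(w)
      sprintf("[%g,%g)", w[1], w[2])), collapse = " "), "\n")
  if (x$doxorubicin_nM > 0)
    cat("  doxorubicin ", x$doxorubicin_nM, " nM at ",
        x$drug_addition_time_min, " min\n", sep = "")
  if (x$cycloheximide) cat("  + cycloheximide\n")
  if (!is.null(x$meki_time_min))
    cat("  + MEK inhibitor at ", x$meki_time_min, " min\n", sep = "")
  invisible(x)
}
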