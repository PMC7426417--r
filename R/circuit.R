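#' Describe a SynIEG circuit
#'
#' A SynIEG combines a serum-responsive promoter (the FOS proximal
#' enhancer/promoter in all circuits modeled here), 5' and 3' UTR elements,
#' an optional Erk-stabilized degron, a fluorescent reporter, and a number
#' of genomic integration sites, each of which transcribes independently and
#' appears as a distinct nuclear focus in the MCP channel.
#'
#' The regulatory consequences of each part:
#' * `utr3 = "FOS"`: the transcript is destabilized by the Erk-induced
#'   Zfp36-like repressor.
#' * `utr3 = "BTG2"`: translation is repressed by miR-21; DNA damage
#'   relieves the repression (the basis of the AND gate).
#' * `utr3 = "TUBULIN"`: neutral control 3' UTR.
#' * `degron = "FRA1"`: adds an Erk-suppressible protein decay route, the
#'   protein-level arm of the FOS duration filter.
#' * `reporter`: `"msfYFP"` (stable) or `"dGFP"` (destabilized, ~10x faster
#'   turnover, resetting to a low starved baseline).
#' * `mir21_status`: `"ENDOGENOUS"`, `"OVEREXPRESSED"` (damage relief
#'   disabled) or `"SPONGE"` (miR-21 titrated away, repression lifted).
#'
#' @param promoter Promoter; only `"FOS"` is modeled.
#' @param utr5 5' element: `"FOS"` or `"BTG2"` (both use the same
#'   transcription law, scaled by `utr5_scale_btg2` in [kinetic_params()]).
#' @param utr3 3' UTR: `"FOS"`, `"BTG2"` or `"TUBULIN"`.
#' @param degron `"NONE"` or `"FRA1"`.
#' @param reporter `"msfYFP"` or `"dGFP"`.
#' @param n_sites Number of genomic integration sites (>= 1).
#' @param mir21_status miR-21 background, see above.
#' @return An object of class `circuit_spec`.
#' @seealso [circuit_preset()] for the named circuits.
#' @export
circuit_spec <- function(promoter = "FOS", utr5 = "FOS", utr3 = "TUBULIN",
                         degron = "NONE", reporter = "msfYFP",
                         n_sites = 8, mir21_status = "ENDOGENOUS") {
  match_enum(promoter, "FOS", "promoter")
  match_enum(utr5, c("FOS", "BTG2"), "utr5")
  match_enum(utr3, c("FOS", "BTG2", "TUBULIN"), "utr3")
  match_enum(degron, c("NONE", "FRA1"), "degron")
  match_enum(reporter, c("msfYFP", "dGFP"), "reporter")
  match_enum(mir21_status, c("ENDOGENOUS", "OVEREXPRESSED", "SPONGE"),
             "mir21_status")
  stopifnot_scalar_number(n_sites, "n_sites", min = 1)
  if (n_sites != round(n_sites))
    abort_validation("`n_sites` must be an integer")
  structure(list(promoter = promoter, utr5 = utr5, utr3 = utr3,
                 degron = degron, reporter = reporter,
                 n_sites = as.integer(n_sites),
                 mir21_status = mir21_status),
            class = "circuit_spec")
}

#' Named SynIEG circuit presets
#'
#' The seven circuits characterized in the study this package models,
#' named `<5' element>-<3' element>`:
#' `fos_tubulin`, `fos_btg2`, `fos_fos`, `btg2_fos`, `btg2_btg2`,
#' `fos_fra1deg_fos` (FOS 3' UTR plus the Fra1 degron, the full duration
#' filter) and `and_gate` (FOS promoter/5' UTR, BTG2 3' UTR, destabilized
#' GFP reporter).
#'
#' @param name Preset name.
#' @param ... Overrides passed to [circuit_spec()] fields (e.g.
#'   `reporter = "dGFP"`, `mir21_status = "SPONGE"`).
#' @return A [circuit_spec()].
#' @export
circuit_preset <- function(name, ...) {
  base <- switch(match_enum(name, circuit_preset_names(), "name"),
    fos_tubulin     = list(utr5 = "FOS", utr3 = "TUBULIN"),
    fos_btg2        = list(utr5 = "FOS", utr3 = "BTG2"),
    fos_fos         = list(utr5 = "FOS", utr3 = "FOS"),
    btg2_fos        = list(utr5 = "BTG2", utr3 = "FOS"),
    btg2_btg2       = list(utr5 = "BTG2", utr3 = "BTG2"),
    fos_fra1deg_fos = list(utr5 = "FOS", utr3 = "FOS", degron = "FRA1"),
    and_gate        = list(utr5 = "FOS", utr3 = "BTG2", reporter = "dGFP"))
  do.call(circuit_spec, utils::modifyList(base, list(...)))
}

circuit_preset_names <- function() {
  c("fos_tubulin", "fos_btg2", "fos_fos", "btg2_fos", "btg2_btg2",
    "fos_fra1deg_fos", "and_gate")
}

#' Kinetic rate constants of the SynIEG model
#'
#' Defaults are the package's shipped parameter set, fixed once by
#' [calibrate_defaults()] against the observed summary behaviors of the
#' circuits (transcription peaking ~30 min after stimulation and adapting
#' within 90 min; ~40% 3-h protein increase for fos-tubulin and ~20% for
#' fos-Fra1deg-fos under sustained light; a roughly fourfold AND-gate
#' response to serum plus doxorubicin with weak single-input responses).
#' All rates are per minute; amounts are arbitrary fluorescence units (a.u.).
#'
#' @param k_tx Transcription rate scale per integration site (a.u./min).
#' @param k_act,k_deact Promoter/Erk-response activation and deactivation
#'   rates (1/min). Activation is first-order while the stimulus is on;
#'   after stimulus removal the engaged state decays at `k_deact`
#'   (transcriptional commitment).
#' @param k_z,delta_z Synthesis and decay rates of the Zfp36-like
#'   adaptation repressor (1/min). Repressor synthesis requires ongoing
#'   protein synthesis (blocked by cycloheximide).
#' @param K_z,h Repression threshold (a.u.) and Hill exponent (>= 1).
#' @param delta_m0 Basal mRNA decay (1/min).
#' @param alpha_fos,K_deg Gain and half-saturation of Zfp36-dependent
#'   destabilization of FOS-3'UTR transcripts.
#' @param k_tl Translation rate (1/min).
#' @param eps_min Residual translation efficiency under full miR-21
#'   repression (in `[0, 1)`).
#' @param k_D DNA-damage signal rise rate after doxorubicin (1/min).
#' @param delta_p0_yfp,delta_p0_dgfp Basal reporter decay rates (1/min);
#'   dGFP must turn over faster than msfYFP.
#' @param delta_deg Additional decay conferred by the Fra1 degron (1/min).
#' @param f_stab Fraction of the degron decay route suppressed by Erk
#'   phosphorylation (in `[0, 1)`).
#' @param m_over,m_sponge miR-21 activity multipliers for the
#'   overexpression and sponge backgrounds.
#' @param p_basal_yfp,p_basal_dgfp Homeostatic baseline reporter level after
#'   starvation (a.u.); protein decay acts on the excess over this pool.
#' @param utr5_scale_btg2 Transcription scale factor for circuits using the
#'   BTG2 5' element (serum responses of these circuits match the FOS 5'
#'   element, hence default 1).
#' @param tele_k_on,tele_k_off Switching-rate scale of the optional
#'   two-state (telegraph) stochastic transcription mode.
#' @return An object of class `kinetic_params`.
#' @export
kinetic_params <- function(k_tx = 1,
                           k_act = 0.019,
                           k_deact = 0.027,
                           k_z = 0.023,
                           delta_z = 0.012,
                           K_z = 0.25,
                           h = 4,
                           delta_m0 = 0.05,
                           alpha_fos = 1.86013,
                           K_deg = 0.3,
                           k_tl = 0.02,
                           eps_min = 0.05,
                           k_D = 0.02,
                           delta_p0_yfp = 8e-4,
                           delta_p0_dgfp = 8e-3,
                           delta_deg = 8e-3,
                           f_stab = 0.9,
                           m_over = 5,
                           m_sponge = 0,
                           p_basal_yfp = 107.6327,
                           p_basal_dgfp = 3.94867,
                           utr5_scale_btg2 = 1,
                           tele_k_on = 0.3,
                           tele_k_off = 0.3) {
  p <- as.list(environment())
  for (nm in names(p)) stopifnot_scalar_number(p[[nm]], nm, min = 0)
  if (p$h < 1) abort_validation("`h` must be >= 1")
  if (p$eps_min >= 1) abort_validation("`eps_min` must be < 1")
  if (p$f_stab >= 1) abort_validation("`f_stab` must be < 1")
  if (p$delta_p0_dgfp <= p$delta_p0_yfp)
    abort_validation("dGFP must be less stable than msfYFP (delta_p0_dgfp > delta_p0_yfp)")
  structure(p, class = "kinetic_params")
}

#' Shipped default kinetic parameters
#'
#' @return The default [kinetic_params()] set (the output of
#'   [calibrate_defaults()] committed as package defaults).
#' @export
default_kinetic_params <- function() kinetic_params()

as_kinetic_params <- function(x) {
  if (inherits(x, "kinetic_params")) return(x)
  if (is.list(x)) return(do.call(kinetic_params, x))
  abort_validation("expected a kinetic_params object")
}

reporter_decay <- function(spec, params) {
  if (spec$reporter == "dGFP") params$delta_p0_dgfp else params$delta_p0_yfp
}

reporter_basal <- function(spec, params) {
  if (spec$reporter == "dGFP") params$p_basal_dgfp else params$p_basal_yfp
}

# translation efficiency under miR-21 regulation of the BTG2 3' UTR.
# Repression strength R in [0,1]; damage relieves repression in the
# endogenous and sponge backgrounds but not under overexpression.
translation_efficiency <- function(spec, params, damage) {
  if (spec$utr3 != "BTG2") return(rep(1, length(damage)))
  R <- switch(spec$mir21_status,
    ENDOGENOUS    = 1 - damage,
    SPONGE        = pmin(1, params$m_sponge * (1 - damage)),
    OVEREXPRESSED = rep(pmin(1, params$m_over), length(damage)))
  1 - (1 - params$eps_min) * R
}

#' Simulate a SynIEG circuit
#'
#' Integrates the multi-step regulation model on the signal time grid.
#' State variables: promoter/Erk-response activation `A`, the Zfp36-like
#' adaptation repressor `Z`, mRNA `M` and reporter protein `P`, with
#' per-site transcription rate
#' `T_i(t) = k_tx * A(t) * K_z^h / (K_z^h + Z(t)^h)`:
#'
#' \deqn{dA/dt = k_{act} E (1-A) - k_{deact} (1-E) A}
#' \deqn{dZ/dt = k_z A S - \delta_z Z}
#' \deqn{dM/dt = \sum_i T_i - \delta_m(Z) M}
#' \deqn{dP/dt = k_{tl} \epsilon(t) M - \delta_p(E) (P - P_{basal})}
#'
#' where \eqn{\delta_m = \delta_{m0}(1 + \alpha_{fos} Z/(K_{deg}+Z))} for
#' FOS-3'UTR transcripts (basal otherwise), \eqn{\epsilon(t)} is the
#' miR-21-dependent translation efficiency of BTG2-3'UTR transcripts
#' (damage-relieved; see [circuit_spec()]), and
#' \eqn{\delta_p = \delta_{p0} + \delta_{deg}(1 - f_{stab} E)} when the
#' Fra1 degron is present (\eqn{\delta_{p0}} otherwise). Protein decay acts
#' on the excess over the homeostatic starved baseline \eqn{P_{basal}}, so
#' an unstimulated trace stays flat at its baseline. A MEK inhibitor forces
#' `E = 0` exactly (see [make_stimulus()]), which zeroes `T_i` through `A`'s
#' collapse and the explicit inhibitor gate on `T`.
#'
#' With `seed` set, per-site transcription is replaced by a seeded two-state
#' telegraph process whose on-rate scales with
#' `E * K_z^h/(K_z^h + Z^h)` (off-rate `tele_k_off`); the deterministic
#' solution is used for `A`, `Z` and the telegraph intensity envelope, and
#' `M`, `P` are then integrated on the grid. The deterministic mode is the
#' reference behavior.
#'
#' @param spec A [circuit_spec()].
#' @param params A [kinetic_params()] set.
#' @param signals A `pathway_signals` object from [make_stimulus()].
#' @param seed Optional integer enabling the stochastic transcription mode.
#' @param init Optional named list overriding initial state
#'   (`A`, `Z`, `M`, `P`); by default `A = Z = M = 0` and
#'   `P = p_basal` for the circuit's reporter.
#' @param rtol Relative tolerance of the stiff integrator (deSolve lsoda).
#' @return A `trajectory`: a data frame with columns `time_min`, `erk`,
#'   `damage`, `act`, `Z`, `T_site1..n`, `mRNA`, `protein`, carrying the
#'   spec, params and stimulus onset as attributes.
#' @examples
#' sig <- make_stimulus(stimulus_preset("serum10"))
#' traj <- simulate_circuit(circuit_preset("fos_btg2"), signals = sig)
#' traj$time_min[which.max(traj$T_site1)]  # transcription peaks ~40 (30 after onset)
#' @export
simulate_circuit <- function(spec, params = default_kinetic_params(),
                             signals, seed = NULL, init = NULL,
                             rtol = 1e-8) {
  if (!inherits(spec, "circuit_spec"))
    abort_validation("`spec` must be a circuit_spec")
  params <- as_kinetic_params(params)
  if (!inherits(signals, "pathway_signals"))
    abort_validation("`signals` must come from make_stimulus()")
  tg <- signals$time_min
  if (!is_uniform_grid(tg))
    abort_validation("signal time grid must be uniform")

  k_tx <- params$k_tx *
    (if (spec$utr5 == "BTG2") params$utr5_scale_btg2 else 1)
  S_flag <- signals$synthesis[1]
  erk_fun <- stats::approxfun(tg, signals$erk, method = "constant",
                              rule = 2, f = 0)
  dam_fun <- stats::approxfun(tg, signals$damage, method = "linear", rule = 2)
  dp0 <- reporter_decay(spec, params)
  pb <- reporter_basal(spec, params)

  y0 <- c(A = 0, Z = 0, M = 0, P = pb)
  if (!is.null(init)) {
    bad <- setdiff(names(init), names(y0))
    if (length(bad))
      abort_validation("unknown init state(s): %s", paste(bad, collapse = ", "))
    y0[names(init)] <- unlist(init)
    if (any(y0 < 0)) abort_validation("initial state must be nonnegative")
  }

  eps_fun <- function(D) translation_efficiency(spec, params, D)
  dm_fun <- function(Z) {
    params$delta_m0 *
      (if (spec$utr3 == "FOS") 1 + params$alpha_fos * Z / (params$K_deg + Z)
       else 1)
  }
  dp_fun <- function(E) {
    dp0 + (if (spec$degron == "FRA1")
      params$delta_deg * (1 - params$f_stab * E) else 0)
  }

  # A MEK inhibitor blocks transcription exactly and immediately: the
  # committed promoter state A cannot sustain transcription without Erk.
  # Stimulus removal (light off), in contrast, leaves A to decay at k_deact.
  meki_t <- if (!is.null(signals$program))
    signals$program$meki_time_min %||% Inf else Inf

  rhs <- function(t, y, parms) {
    E <- erk_fun(t); D <- dam_fun(t)
    A <- y[1]; Z <- max(y[2], 0); M <- max(y[3], 0); P <- y[4]
    hill <- params$K_z^params$h / (params$K_z^params$h + Z^params$h)
    Tr <- if (t >= meki_t) 0 else k_tx * A * hill
    dA <- params$k_act * E * (1 - A) - params$k_deact * (1 - E) * A
    dZ <- params$k_z * A * S_flag - params$delta_z * Z
    dM <- spec$n_sites * Tr - dm_fun(Z) * M
    dP <- params$k_tl * eps_fun(D) * M - dp_fun(E) * (P - pb)
    list(c(dA, dZ, dM, dP))
  }

  sol <- deSolve::ode(y = y0, times = tg, func = rhs, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = 1e-10)
  sol <- as.data.frame(sol)
  A <- pmax(sol$A, 0); Z <- pmax(sol$Z, 0)
  M <- pmax(sol$M, 0); P <- pmax(sol$P, 0)
  hill <- params$K_z^params$h / (params$K_z^params$h + Z^params$h)
  gate <- as.numeric(tg < meki_t)
  T_det <- k_tx * A * hill * gate

  n <- spec$n_sites
  if (is.null(seed)) {
    Tmat <- matrix(rep(T_det, n), ncol = n)
  } else {
    Tmat <- withr::with_seed(as.integer(seed), {
      dt <- signals$dt_min
      sapply(seq_len(n), function(i) {
        state <- 0L
        out <- numeric(length(tg))
        for (k in seq_along(tg)) {
          k_on <- params$tele_k_on * signals$erk[k] * hill[k]
          if (state == 0L) {
            if (stats::runif(1) < 1 - exp(-k_on * dt)) state <- 1L
          } else {
            if (stats::runif(1) < 1 - exp(-params$tele_k_off * dt)) state <- 0L
          }
          out[k] <- state
        }
        k_tx * A * gate * out
      })
    })
    # re-integrate M and P with the stochastic transcription sum (Euler)
    dt <- signals$dt_min
    Tsum <- rowSums(Tmat)
    M <- numeric(length(tg)); P <- numeric(length(tg))
    M[1] <- y0["M"]; P[1] <- y0["P"]
    eps <- eps_fun(signals$damage)
    for (k in seq_len(length(tg) - 1L)) {
      M[k + 1] <- max(0, M[k] + dt * (Tsum[k] - dm_fun(Z[k]) * M[k]))
      P[k + 1] <- max(0, P[k] + dt * (params$k_tl * eps[k] * M[k] -
                                        dp_fun(signals$erk[k]) * (P[k] - pb)))
    }
  }

  traj <- data.frame(time_min = tg, erk = signals$erk,
                     damage = signals$damage, act = A, Z = Z)
  colnames(Tmat) <- paste0("T_site", seq_len(n))
  traj <- cbind(traj, as.data.frame(Tmat))
  traj$mRNA <- M
  traj$protein <- P
  structure(traj,
            class = c("trajectory", "data.frame"),
            spec = spec, params = params,
            stim_onset_min = signals$stim_onset_min,
            dt_min = signals$dt_min,
            seed = seed)
}

#' Columns of the per-site transcription block of a trajectory
#' @param traj A trajectory from [simulate_circuit()].
#' @return Matrix of per-site transcription rates (time x sites).
#' @export
transcription_rates <- function(traj) {
  as.matrix(traj[, grep("^T_site", names(traj)), drop = FALSE])
}

#' Write / read a trajectory as CSV
#'
#' The CSV has columns `time_min, erk, damage, act, Z, T_site1..n, mRNA,
#' protein`. The stimulus onset is stored in a `# stim_onset_min:` header
#' comment so kinetic metrics survive a round trip.
#'
#' @param traj A trajectory.
#' @param path Output file.
#' @return `path`, invisibly (writer); a trajectory (reader).
#' @export
write_trajectory_csv <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# stim_onset_min: %g dt_min: %g",
                     attr(traj, "stim_onset_min") %||% 0,
                     attr(traj, "dt_min") %||% diff(traj$time_min[1:2])),
             con)
  utils::write.csv(as.data.frame(traj), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  hdr <- readLines(path, n = 1L)
  onset <- 0; dt <- NA_real_
  if (startsWith(hdr, "#")) {
    nums <- as.numeric(regmatches(hdr, gregexpr("[0-9.]+", hdr))[[1]])
    if (length(nums) >= 1) onset <- nums[1]
    if (length(nums) >= 2) dt <- nums[2]
  }
  df <- utils::read.csv(path, comment.char = "#")
  structure(df, class = c("trajectory", "data.frame"),
            stim_onset_min = onset,
            dt_min = if (is.na(dt)) diff(df$time_min[1:2]) else dt)
}

#' @export
print.circuit_spec <- function(x, ...) {
  cat(sprintf("<circuit_spec> %s promoter, %s 5', %s 3', degron %s, %s, %d sites, miR-21 %s\n",
              x$promoter, x$utr5, x$utr3, x$degron, x$reporter, x$n_sites,
              x$mir21_status))
  invisible(x)
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("<kinetic_params>\n")
  v <- unlist(x)
  print(v)
  invisible(x)
}
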