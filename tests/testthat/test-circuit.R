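test_that("circuit specs validate and the named circuits are constructible", {
  for (nm in c("fos_tubulin", "fos_btg2", "fos_fos", "btg2_fos",
               "btg2_btg2", "fos_fra1deg_fos", "and_gate"))
    expect_s3_class(circuit_preset(nm), "circuit_spec")
  expect_equal(circuit_preset("and_gate")$reporter, "dGFP")
  expect_equal(circuit_preset("fos_fra1deg_fos")$degron, "FRA1")
  expect_error(circuit_spec(utr3 = "ACTIN"), class = "synieg_validation")
  expect_error(circuit_spec(n_sites = 0), class = "synieg_validation")
  expect_error(kinetic_params(k_tx = -1), class = "synieg_validation")
  expect_error(kinetic_params(eps_min = 1), class = "synieg_validation")
  expect_error(kinetic_params(delta_p0_dgfp = 1e-4),
               class = "synieg_validation")
})

test_that("zero input and zero initial state is absorbing", {
  sig <- quick_signals("starve")
  params <- kinetic_params(p_basal_yfp = 0, p_basal_dgfp = 0)
  traj <- simulate_circuit(circuit_preset("fos_btg2"), params, sig)
  expect_true(all(traj$Z == 0))
  expect_true(all(transcription_rates(traj) == 0))
  expect_true(all(traj$mRNA == 0))
  expect_true(all(traj$protein == 0))
})

test_that("states are nonnegative across randomized circuits and stimuli", {
  set.seed(42)
  presets <- circuit_preset_names <- c("fos_tubulin", "fos_btg2", "fos_fos",
                                       "btg2_fos", "btg2_btg2",
                                       "fos_fra1deg_fos", "and_gate")
  stims <- c("serum10", "serum1", "transient20", "sustained", "dox",
             "serum1_dox")
  for (i in 1:10) {
    base <- unclass(default_kinetic_params())
    jf <- c("k_tx", "k_act", "k_z", "delta_z", "delta_m0", "alpha_fos",
            "k_tl", "delta_deg")
    for (f in jf) base[[f]] <- base[[f]] * exp(rnorm(1, 0, 0.4))
    p <- do.call(kinetic_params, base)
    spec <- circuit_preset(sample(presets, 1))
    sig <- make_stimulus(stimulus_preset(sample(stims, 1)), p)
    traj <- simulate_circuit(spec, p, sig)
    expect_true(all(as.matrix(traj[, -1]) >= 0))
  }
})

test_that("serum plus cycloheximide gives sustained, non-adapting transcription", {
  sig <- quick_signals("serum10", cycloheximide = TRUE)
  traj <- simulate_circuit(circuit_preset("fos_btg2"), signals = sig)
  expect_true(all(traj$Z == 0))
  Tt <- traj$T_site1
  post <- Tt[traj$time_min >= 10]
  # monotone rise toward k_tx, no adaptation
  expect_true(all(diff(post) >= -1e-9))
  expect_gt(post[length(post)], 0.9 * default_kinetic_params()$k_tx)

  # without cycloheximide the same stimulus adapts after its peak
  traj2 <- simulate_circuit(circuit_preset("fos_btg2"),
                            signals = quick_signals("serum10"))
  T2 <- traj2$T_site1
  pk <- which.max(T2)
  expect_true(all(diff(T2[seq_len(pk)]) >= -1e-9))
  expect_true(all(diff(T2[pk:length(T2)]) <= 1e-9))
  expect_lt(T2[length(T2)], 0.05 * max(T2))
})

test_that("MEK inhibition zeroes transcription exactly from the inhibition time", {
  sig <- quick_signals("serum10", meki_time_min = 40)
  traj <- simulate_circuit(circuit_preset("fos_btg2"), signals = sig)
  expect_true(all(transcription_rates(traj)[traj$time_min >= 40, ] == 0))
  expect_true(all(transcription_rates(traj)[traj$time_min > 10 &
                                              traj$time_min < 40, ] > 0))
})

test_that("clamped-repressor steady state matches the analytic fixed point", {
  p <- kinetic_params(k_z = 0, p_basal_yfp = 0, p_basal_dgfp = 0,
                      delta_p0_yfp = 0.01, delta_p0_dgfp = 0.1)
  prog <- stimulus_program(20000, dt_min = 20, serum_fraction = 0.10)
  sig <- make_stimulus(prog, p)
  spec <- circuit_spec(utr3 = "TUBULIN", degron = "NONE", n_sites = 8)
  traj <- simulate_circuit(spec, p, sig)
  M_star <- spec$n_sites * p$k_tx / p$delta_m0
  P_star <- p$k_tl * M_star / p$delta_p0_yfp
  n <- nrow(traj)
  expect_equal(traj$mRNA[n], M_star, tolerance = 1e-4)
  expect_equal(traj$protein[n], P_star, tolerance = 1e-3)
})

test_that("fold-change of fos-tubulin is duration-insensitive", {
  f <- function(preset) {
    fold_change(protein_trace(simulate_circuit(
      circuit_preset("fos_tubulin"), signals = quick_signals(preset))))$fold
  }
  fs <- f("sustained"); ft <- f("transient20")
  expect_lt(abs(fs / ft - 1), 0.15)
})

test_that("protein fold-change is non-decreasing in light duration for the duration filter", {
  spec <- circuit_preset("fos_fra1deg_fos")
  folds <- sapply(c(10, 20, 45, 90, 180), function(d) {
    prog <- stimulus_program(190, 2, light_windows = list(c(10, 10 + d)),
                             drug_addition_time_min = 10)
    fold_change(protein_trace(simulate_circuit(
      spec, signals = make_stimulus(prog))))$fold
  })
  expect_true(all(diff(folds) > -1e-9))
})

test_that("the degron circuit is more duration-selective than fos-tubulin", {
  ratio <- function(name) {
    f <- function(preset)
      fold_change(protein_trace(simulate_circuit(
        circuit_preset(name), signals = quick_signals(preset))))$fold
    f("sustained") / f("transient20")
  }
  expect_gt(ratio("fos_fra1deg_fos"), ratio("fos_tubulin"))
})

test_that("miR-21 backgrounds order the serum response: sponge > endogenous >= overexpressed", {
  f <- function(status)
    fold_change(protein_trace(simulate_circuit(
      circuit_preset("fos_btg2", mir21_status = status),
      signals = quick_signals("serum10"))))$fold
  sponge <- f("SPONGE"); endo <- f("ENDOGENOUS"); over <- f("OVEREXPRESSED")
  expect_gt(sponge, endo)
  expect_gte(endo, over)
})

test_that("the AND gate is super-additive and the fos-fos control is additive", {
  dP <- function(name, preset) {
    tr <- protein_trace(simulate_circuit(circuit_preset(name),
                                         signals = quick_signals(preset)))
    tr$values[length(tr$values)] - trace_baseline(tr)
  }
  ab <- dP("and_gate", "serum1_dox")
  a <- dP("and_gate", "serum1")
  b <- dP("and_gate", "dox")
  expect_gt(ab, a + b)
  expect_gt(ab, 2 * (a + b))  # strongly super-additive with shipped defaults

  # fos-fos: no translational gate, so serum+dox adds nothing over serum
  ctrl <- circuit_preset("fos_fos", reporter = "dGFP")
  tr_ab <- protein_trace(simulate_circuit(ctrl,
                                          signals = quick_signals("serum1_dox")))
  tr_a <- protein_trace(simulate_circuit(ctrl,
                                         signals = quick_signals("serum1")))
  tr_b <- protein_trace(simulate_circuit(ctrl,
                                         signals = quick_signals("dox")))
  dab <- tr_ab$values[length(tr_ab$values)] - trace_baseline(tr_ab)
  da <- tr_a$values[length(tr_a$values)] - trace_baseline(tr_a)
  db <- tr_b$values[length(tr_b$values)] - trace_baseline(tr_b)
  expect_lt(abs(dab - (da + db)) / abs(dab), 0.1)
})

test_that("stochastic transcription mode is seeded and reproducible", {
  sig <- quick_signals("serum10")
  spec <- circuit_preset("fos_btg2", n_sites = 4)
  t1 <- simulate_circuit(spec, signals = sig, seed = 7)
  t2 <- simulate_circuit(spec, signals = sig, seed = 7)
  t3 <- simulate_circuit(spec, signals = sig, seed = 8)
  expect_identical(transcription_rates(t1), transcription_rates(t2))
  expect_false(identical(transcription_rates(t1), transcription_rates(t3)))
  expect_true(all(as.matrix(t1[, -1]) >= 0))
  # sites burst independently
  Tm <- transcription_rates(t1)
  expect_false(identical(Tm[, 1], Tm[, 2]))
})

test_that("trajectory CSV round trip preserves the data and onset", {
  sig <- quick_signals("serum10")
  traj <- simulate_circuit(circuit_preset("fos_btg2", n_sites = 3),
                           signals = sig)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(traj, path)
  back <- read_trajectory_csv(path)
  expect_equal(plain_df(back), plain_df(traj), tolerance = 1e-12)
  expect_equal(attr(back, "stim_onset_min"), attr(traj, "stim_onset_min"))
})

test_that("simulation rejects malformed inputs", {
  sig <- quick_signals("serum10")
  sig$time_min[3] <- sig$time_min[3] + 0.5   # break uniformity
  expect_error(simulate_circuit(circuit_preset("fos_btg2"), signals = sig),
               class = "synieg_validation")
  expect_error(simulate_circuit(circuit_preset("fos_btg2"),
                                signals = quick_signals("serum10"),
                                init = list(P = -1)),
               class = "synieg_validation")
})
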