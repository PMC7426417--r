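# synieg

Simulation and quantification of synthetic immediate-early gene (SynIEG)
circuits.

SynIEGs are transgenes that pair an Erk-responsive promoter with
exchangeable mRNA UTR elements, protein degrons and a fluorescent
reporter carrying MS2 stem-loops, so that both nascent transcription
(nuclear MCP foci) and protein output can be followed in single live
cells. Combining parts from different immediate-early genes yields
circuits that *decode* upstream signaling: a duration filter built from
FOS regulation (Zfp36-mediated mRNA destabilization plus an
Erk-stabilized Fra1 degron responds to sustained but not transient Erk)
and a two-input AND gate built from the FOS promoter and the
miR-21-repressed BTG2 3' UTR (serum drives transcription, DNA damage
relieves translational repression — protein accumulates only with both).

This package is for researchers modeling such circuits or validating
transcription-site quantification pipelines. It provides:

* **`circuit_model`** — a deterministic (optionally stochastic/telegraph)
  kinetic model of SynIEG regulation under programmable serum, light,
  doxorubicin, cycloheximide and MEK-inhibitor schedules. Core states:
  promoter activation *A*, Zfp36-like repressor *Z*, per-site
  transcription rate *T_i = k_tx·A·K_z^h/(K_z^h+Z^h)*, mRNA *M*,
  protein *P*, with UTR-dependent mRNA decay, miR-21-gated translation
  ε(t) and degron-dependent protein decay.
* **`movie_synth`** — rendering of trajectories into T×Z×C×Y×X synthetic
  movies (nuclear marker / MCP foci / diffuse reporter; 7 z-slices at
  0.8 µm) with Poisson photon noise, read noise and camera offset;
  bit-identical under a fixed seed, with ground truth attached.
* **`burst_quant`** — the transcription-site chain: z max-projection,
  LoG focus detection, stationary-site tracking, axis-aligned 2D
  Gaussian fits with integrated burst intensity *I = 2πAσxσy*.
* **`trace_analysis`** — nuclear mean traces, the baseline-anchored
  AUC = Σ_t (intensity(t) − initial) with the baseline from the first
  two timepoints, fold-changes, kinetic timing metrics, per-condition
  aggregation.
* **`decoding_stats`** — duration-filter index, AND-gate synergy
  S = AUC(AB) − AUC(A) − AUC(B) with classification, and two-sided
  t-tests (pooled Student by default, Welch/paired by flag).
* **`cli_io`** — YAML/JSON configs, CSV/TIFF/JSON writers, the
  `pipeline_*()` stage functions, and a thin command-line wrapper at
  `inst/cli/synieg`.

## Worked example

Simulate the default fos-btg2 reporter line under 10% serum, render a
synthetic movie, and quantify its transcriptional foci:

```r
library(synieg)

params <- default_kinetic_params()
sig    <- make_stimulus(stimulus_preset("serum10"), params)
traj   <- simulate_circuit(circuit_preset("fos_btg2"), params, sig)
movie  <- render_movie(traj, cell_geometry(), optics_noise(), seed = 3)

dt <- detect_and_track(movie)
length(dt$tracks)
#> [1] 8

b  <- burst_traces(movie, dt$tracks)
mb <- mean_trace(b$traces)
kinetic_metrics(mb, noise_sd = pooled_prestim_noise_sd(b$traces))
#> $time_to_peak_min
#> [1] 30
#> $adaptation_time_min
#> [1] 76
```

Eight transcriptional foci — one per genomic integration site — are
recovered; their mean integrated burst intensity peaks 30 min after
serum addition and returns to baseline within 90 min, the signature
adaptive pulse of an immediate-early gene.

Scoring the AND gate on a simulated population (12 cells per condition,
20% cell-to-cell parameter CV):

```r
simulate_gate_experiment(n_cells = 12, cv = 0.2, seed = 1)
#> <gate_report>
#>   mean AUC: starve=0 (n=12), A=93.01 (n=12), B=0 (n=12), AB=1149 (n=12)
#>   synergy S = 1056
#>   single-input folds: A=1.2, B=1 (tau=1.5)
#>   starve_vs_A  p = 1.57e-12 ***
#>   starve_vs_B  p = 1 ns
#>   starve_vs_AB p = 8.35e-12 ***
#>   A_vs_AB      p = 4.52e-11 ***
#>   B_vs_AB      p = 8.35e-12 ***
#>   classification: AND-like
```

Serum alone gives a weak response (1.2-fold, below the τ = 1.5
threshold), doxorubicin alone none, and the combination a strongly
super-additive response — the engineered AND-gate behavior.

The methods vignette (`vignettes/synieg-methods.Rmd`) documents the
model equations, the calibration of the shipped defaults, the noise
model, and the robustness rules of the Gaussian fitting chain.

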