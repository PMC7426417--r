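---
title: "Modeling and quantifying synthetic immediate-early gene circuits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and quantifying synthetic immediate-early gene circuits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synieg)
```

## Background

Synthetic immediate-early genes (SynIEGs) are transgenes that combine an
Erk-responsive promoter, 5'/3' UTR elements, optional protein degrons and
a fluorescent reporter carrying MS2 stem-loops. In live cells, nascent
transcription at each genomic integration site is visible as a bright
nuclear MCP focus, and protein output as diffuse reporter fluorescence.
By mixing and matching parts, such circuits implement *multi-step
decoding* of upstream signals: a duration filter (FOS-like regulation:
Zfp36-mediated mRNA destabilization plus an Erk-stabilized Fra1 degron)
and a two-input AND gate (FOS promoter plus the miR-21-repressed BTG2
3' UTR, de-repressed by DNA damage).

This package provides a deterministic kinetic model of these circuits, a
renderer that turns simulated trajectories into realistic synthetic
movies, and the quantification chain used on real data (max projection,
2D Gaussian burst fitting, nuclear traces, baseline-anchored AUC and
fold-change statistics, gate/filter scoring). Because the renderer knows
its ground truth, every stage of the quantification chain can be
validated against known inputs without any external data.

## The kinetic model

For a circuit with $n$ integration sites driven by normalized Erk input
$E(t) \in \{0,1\}$, DNA-damage signal $D(t)$, and protein-synthesis
indicator $S \in \{0,1\}$ (0 under cycloheximide):

$$
\begin{aligned}
\frac{dA}{dt} &= k_{act}\,E\,(1-A) - k_{deact}\,(1-E)\,A \\
T_i(t) &= k_{tx}\,A(t)\,\frac{K_z^h}{K_z^h + Z(t)^h} \\
\frac{dZ}{dt} &= k_z\,A\,S - \delta_z\,Z \\
\frac{dM}{dt} &= \sum_i T_i - \delta_m(Z)\,M \\
\frac{dP}{dt} &= k_{tl}\,\epsilon(t)\,M - \delta_p(E)\,(P - P_{basal})
\end{aligned}
$$

with $\delta_m = \delta_{m0}\,(1 + \alpha_{fos}\,Z/(K_{deg}+Z))$ for
FOS-3'UTR transcripts and $\delta_{m0}$ otherwise;
$\epsilon = 1$ for non-BTG2 3' UTRs and
$\epsilon = \epsilon_{min} + (1-\epsilon_{min})\,D(t)$ for the BTG2
3' UTR in the endogenous miR-21 background ($\epsilon = 1$ with the
miR-21 sponge, pinned at $\epsilon_{min}$ under miR-21 overexpression);
and $\delta_p = \delta_{p0} + \delta_{deg}(1 - f_{stab} E)$ when the
Fra1 degron is present, $\delta_{p0}$ otherwise. Time is in minutes and
amounts in arbitrary fluorescence units throughout.

Three modeling choices deserve comment:

**Promoter engagement and commitment ($A$).** Observed focus intensity
rises over tens of minutes after stimulation and peaks near 30 min,
which a step input multiplied into a repression term cannot produce (it
would peak immediately). $A(t)$ models the lumped kinetics of promoter
engagement downstream of Erk with activation rate $k_{act}$. Its decay
after stimulus removal ($k_{deact}$, half-life ~25 min) encodes
*transcriptional commitment*: a brief light pulse triggers nearly the
same transcriptional output as sustained light, which is exactly why the
neutral fos-tubulin circuit accumulates similar protein under transient
and sustained stimulation while the full filter discriminates them. A
MEK inhibitor, in contrast, gates transcription to exactly zero from the
moment of addition: pharmacological pathway inhibition acts downstream
of commitment.

**Degron decay is additive.** The Fra1 degron contributes its own
Erk-suppressible decay route $\delta_{deg}(1-f_{stab}E)$ on top of the
reporter's basal turnover. Making the degron merely modulate the basal
rate would render it inert for a stable YFP; the additive form reflects
the biology (the degron destabilizes the protein unless Erk
phosphorylates it) and gives the duration filter its protein-level arm.

**Baseline homeostasis.** Protein decay acts on the excess over the
starved baseline pool $P_{basal}$. Starved and damage-only traces
therefore stay flat at baseline rather than decaying to zero, matching
the behavior of starved reporter lines, and a circuit with zero input
and zero initial state stays identically at zero.

### Shipped defaults and calibration

The default parameters in `kinetic_params()` were fixed once by
`calibrate_defaults()`, which searches the transcription-shape
parameters on a coarse grid (solving the output-scale parameters by
fixed-point iteration at each point) and refines locally, against the
study's printed summary behaviors:

* serum-stimulated transcription peaks ≈ 30 min after stimulation and
  returns to near baseline within 90 min;
* fos-tubulin gains ≈ 40% protein over 3 h of sustained light, and the
  full filter (fos-Fra1deg-fos) ≈ 20%;
* the AND gate responds ≈ fourfold to serum + doxorubicin at 3 h while
  each single input stays below 1.5-fold.

All constraints are met within a 15% relative tolerance (most exactly).
Within those constraints the feasible region is narrow: transcriptional
commitment ($k_{deact}$) trades off against the monotonicity of the
duration response, and repressor speed against peak time, which is why
the defaults are committed rather than re-derived per run. An
infeasible constraint set (e.g. demanding a 30-min peak *and*
non-adapting transcription with protein synthesis intact) makes
`calibrate_defaults()` fail loudly with its best residuals — adaptation
is structural whenever the repressor is produced.

The stimulus presets include a 10-minute starved lead-in before
stimulation so that every trace has pre-stimulus frames; baselines
(mean of the first two timepoints) and pre-stimulus noise estimates are
anchored there, and kinetic metrics are reported relative to the
stimulation time.

An optional seeded two-state (telegraph) transcription mode replaces the
deterministic per-site rate with stochastic bursting whose on-rate
scales with the same activation/repression terms; it is useful for
exploring focus-to-focus variability but the deterministic solution is
the package's reference behavior.

## Movie synthesis

`render_movie()` converts a trajectory into a T×Z×C×Y×X stack with
three channels (nuclear marker, MCP transcription foci, diffuse
reporter), 7 z-slices spaced 0.8 µm, defaulting to a 128×128 px field at
0.27 µm/px and 2-min frames. Each focus receives total expected photons
proportional to its site's instantaneous transcription rate,
distributed axially by a Gaussian profile normalized over the 7
acquired slices — so the collected photon sum is independent of the
site's z position — and laterally by a Gaussian PSF (σ = 1.3 px).
Expected photons are Poisson-sampled; Gaussian read noise and a camera
offset are added; values are clipped to the bit depth. Rendering is
bit-identical for a fixed seed.

A note on the axial extent: 7 slices at 0.8 µm spacing span 4.8 µm
(6 gaps × 0.8 µm); descriptions of this acquisition scheme sometimes
quote 4.5 µm, which is arithmetically inconsistent with the stated
spacing. The renderer implements 7 × 0.8 µm.

What the generator deliberately does *not* emulate: photobleaching,
cell motion and division, multi-cell fields, nascent-chain dwell-time
convolution of focus intensity (focus brightness is taken proportional
to the instantaneous transcription rate), and optical aberrations.
Passing tests on synthetic movies therefore validate the quantification
chain's correctness and calibration, not its robustness to these
real-data complications.

`jitter_population()` emulates cell-to-cell variability by log-normal
jitter (unit mean, chosen CV) of the expression-scale parameters —
transcription/translation rates, mRNA and reporter turnover, baseline
pools — with per-cell re-sampled site positions. Signaling-timing
constants are shared across the population, as expected for a clonal
line driven by a common pathway; a default CV of 0.2 reproduces the
order of spread seen between cells of one clone.

## Burst quantification

The chain mirrors the standard transcription-site workflow:

1. **Max projection** of the MCP z-stack per frame, so all foci lie in
   one plane.
2. **Detection** by scale-normalized Laplacian-of-Gaussian filtering
   restricted to the nucleus, thresholded at median + 5 MAD of the
   masked response, with non-maximum suppression at 6 px. Candidates
   are restricted to the mask eroded by the kernel radius because the
   nuclear rim is a brightness step that rings under the filter. When
   the MAD degenerates (noise-free images) the SD takes its place.
3. **Tracking** by greedy nearest-neighbour linking (≤ 3 px
   displacement, ≤ 3-frame gaps, ≥ 8 frames), appropriate for
   stationary integration sites. Manually marked positions can be
   supplied instead, mimicking a Fiji-based workflow.
4. **2D Gaussian fitting** at each track's mean position on every
   frame: an axis-aligned Gaussian with free background, amplitude,
   centre and widths over a 9×9 ROI, widths bounded in [0.5, 4] px.
   The burst intensity is the integrated area above background,
   $I = 2\pi A \sigma_x \sigma_y$.

Two robustness rules matter in practice. A *flat* ROI (no amplitude)
is a failed fit and is recorded as missing — never as zero, which
would bias means. A free-width fit that runs into its width bounds has
latched onto background structure rather than a focus; it is retried
with the widths pinned at the PSF scale, so burst-free frames report
small near-zero intensities and baselines remain well defined. With
these rules the quantified mean trace of the default movie tracks the
true transcription rate with R² > 0.99 (noiseless) and ≈ 0.99 under
realistic noise.

Fitting is axis-aligned rather than rotated: a rotation angle adds a
parameter without improving integrated-intensity recovery for
PSF-shaped spots. Background is absorbed by the fitted offset rather
than pre-subtracted, which makes the integrated intensity invariant to
constant offsets.

## Trace statistics

* `compute_auc()`: the baseline-anchored plain sum
  $\mathrm{AUC} = \sum_t (\mathrm{intensity}(t) - \mathrm{initial})$
  with the baseline set by averaging the first two timepoints. No
  trapezoid or dt-weighting is applied; units are a.u.·frames. The sum
  runs over all frames including the baseline frames; missing values
  are skipped and counted.
* `fold_change()`: final value over baseline by default (a max-based
  variant is available); percent = 100·(fold − 1).
* `kinetic_metrics()`: time to peak (argmax after stimulation) and
  adaptation time (first post-peak return to within one noise SD of
  baseline). For quantified movies the noise SD should come from
  `pooled_prestim_noise_sd()`, which pools pre-stimulus variance across
  tracks — far more stable than the SD of a handful of mean-trace
  frames.
* `nuclear_mean_trace()`: mean of the masked central z-slice, the
  best-focus proxy for diffuse reporter quantification (nuclear means
  are not computed on projections).

## Decoding statistics

`ttest()` wraps the two-sided Student test (equal-variance pooled by
default, Welch by flag, paired on request) with one convention: when
both groups are constant and equal (or all paired differences are
zero), t = 0 and p = 1. `duration_filter_index()` compares sustained
and transient stimulation via the ratio of mean baseline-subtracted
fold-changes. `gate_analysis()` computes the synergy
$S = \overline{\mathrm{AUC}}_{AB} - \overline{\mathrm{AUC}}_A -
\overline{\mathrm{AUC}}_B$, the t-tests usually reported for such
experiments (starve vs each condition; each single input vs the
combination), and classifies the response:

* **AND-like** — $S > 0$, the combination significantly exceeds each
  single input, and each single-input fold is below τ = 1.5. The
  tolerance for weak single-input responses is deliberate: real
  serum-driven leak through residual translation prevents a perfect
  gate, and a classifier that demanded zero single-input response would
  reject the very behavior being engineered.
* **single-input-driven** — one input alone reaches τ or ≥ 90% of the
  combined response.
* **additive** — everything else (exact additivity gives $S = 0$).

This quantitative AND-gate criterion is an operational definition of
this package and is labeled as such in its JSON report. No
multiple-testing correction is applied, matching the raw starred
p-values such experiments report.

## Numerical choices

* ODE integration: `deSolve::lsoda` with relative tolerance 1e−8
  (stiff-safe; the model is mildly stiff when reporter and mRNA decay
  rates differ by orders of magnitude).
* Gaussian fits: `minpack.lm::nls.lm` bounded Levenberg–Marquardt,
  initialized from ROI maximum and intensity moments; convergence
  requires an interior solution (amplitude above zero, widths strictly
  inside their bounds).
* Degenerate inputs: empty detection lists produce empty track lists;
  all-missing traces, empty masks, non-uniform grids and negative
  rates raise classed validation errors (`synieg_validation`), which
  the command-line wrapper maps to exit code 2 (3 for infeasible
  calibration).
* Randomness: every stochastic step (site placement, photon noise,
  population jitter, telegraph bursting) takes an explicit seed and
  restores the RNG state afterwards; identical seeds give bit-identical
  movies and byte-identical pipeline outputs.

## Problem sizes

The shipped configuration simulates 190 min at 2-min resolution
(96 frames), renders 128×128 px × 7 z × 3 channels, and quantifies 8
foci — a render-and-quantify cycle takes on the order of ten seconds.
The test suite uses 64×64 px movies with 2–4 sites and shortened
timecourses for everything except the final end-to-end checks, and the
population experiments use 12–20 cells per condition at CV 0.2.

## Known limitations

* The model is phenomenological: the Zfp36-like repressor, the damage
  signal and miR-21 relief are lumped first-order processes, and the
  mechanism by which damage relieves BTG2 translational repression is
  represented only through $\epsilon(t)$.
* BTG2-5'-element circuits reuse the FOS transcription law with a unit
  scale factor; no separate promoter kinetics are modeled.
* Reporter maturation, photobleaching and cell-cycle effects are
  outside the generator's scope, so absolute intensities are arbitrary
  units and comparisons are within-configuration.
* The duration-response monotonicity of the full filter holds at the
  shipped defaults but sits in a narrow parameter corridor (commitment
  vs shutoff); refitting the model to other cell lines should re-check
  it via `calibrate_defaults()`.
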