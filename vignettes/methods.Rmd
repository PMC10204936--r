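---
title: "Methods: probe-geometry images and CNN classification of HD FD-fNIRS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: probe-geometry images and CNN classification of HD FD-fNIRS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fnirscnn)
```

This vignette documents the scientific model implemented by `fnirscnn`, the
assumptions behind its synthetic data generator, the numerical choices in
the processing chain, and the rationale for decisions where the method left
room for interpretation.  Problem sizes used below (cohort sizes, numbers
of seeds, epoch counts) are this package's own choices, picked so that the
complete pipeline runs on a single CPU core in minutes.

## 1. The measurement model

Frequency-domain (FD) near-infrared spectroscopy launches intensity-modulated
light (here 141 MHz) into the scalp and records, per source-detector channel
and per wavelength (690 and 830 nm), both the **AC amplitude** and the
**phase delay** of the detected photon-density wave.  Under the diffusion
approximation for a semi-infinite homogeneous medium, the complex fluence at
source-detector separation $\rho$ is

$$\Phi(\rho) \propto \frac{e^{-k \rho}}{\rho}, \qquad
  k = \sqrt{\frac{\mu_a - i\,\omega/v}{D}},$$

with absorption $\mu_a$, reduced scattering $\mu_s'$, diffusion coefficient
$D = 1/(3(\mu_a+\mu_s'))$, modulation frequency $\omega$ and light speed in
tissue $v$.  `fd_semiinfinite_response()` evaluates this expression; its
derivative with respect to $\mu_a$ (`mua_sensitivity()`) yields the
**effective pathlength** used by the modified Beer-Lambert law (MBLL):
$L_{\mathrm{eff}} = \partial(\Delta OD)/\partial\mu_a$.  We derive
pathlengths from the diffusion model at each channel's separation rather
than assuming a fixed differential pathlength factor, so NN1, NN2 and NN3
channels get physically consistent, distance-dependent pathlengths.

Activation changes the concentrations of oxy- and deoxy-haemoglobin
(HbO, Hb), which move $\mu_a$ through tabulated extinction coefficients.
MBLL inverts the two-wavelength optical-density changes to the two
chromophores channel by channel; the inversion is exact linear algebra and
is verified against a forward round-trip in the test suite.

## 2. Probe geometry and channel enumeration

The probe consists of **two checkerboard pads** of alternating sources and
detectors on a 13 mm square pitch: each pad is a 4 × 8 grid (16 sources,
15 detectors after masking the corner at grid position (0, 7)), and the two
pads sit left and right of the midline with a 26 mm gap.  Channels are
source-detector pairs within a pad, classified by separation:

| class | geometry | separation | default count | retained |
|---|---|---|---|---|
| NN1 | lattice neighbours | 13 mm | 100 | yes |
| NN2h | diagonal, horizontal-major | 13√5 ≈ 29.1 mm | 70 | yes |
| NN2v | diagonal, vertical-major | 13√5 ≈ 29.1 mm | 54 | yes |
| NN3 | straight-line skip | 39 mm | 52 | no (> 30 mm) |

`enumerate_channels()` classifies all pairs by distance with a 0.5 mm
tolerance and errors if any pair is ambiguous; the test suite checks it
against a brute-force oracle on random layouts.  NN3 channels are measured
and pass through QC, but are discarded before imaging (their separation
exceeds the 30 mm SNR cutoff).

**Block images.** Each channel's midpoint falls on a half-pitch (6.5 mm)
voxel lattice spanning 7 × 33 voxels across both pads.  Channels of the same
class map to disjoint voxels, so each (chromophore × class) combination forms
one image layer; with HbO/Hb and NN1/NN2h/NN2v this gives a
**6 × T × 7 × 33** tensor per example.  The layout is mirror-symmetric about
the midline column, which makes the **mirror-flip augmentation** exact:
reversing the image width axis maps every channel onto its contralateral
counterpart, and swapping the left/right labels yields a valid new training
example.  `mirror_block()` verifies the symmetry before flipping and is an
involution.

The **Flat** representation stacks all retained channel × plane series as
rows of a matrix (no spatial structure), and **Source-by-Detector** places
series on a source-index × detector-index grid (structure present but
geometrically meaningless); they serve as ablations of the spatial encoding.

## 3. The synthetic cohort generator

No public recordings exist for this probe, so the package bundles a
simulator whose defaults define the study conditions:

- **Paradigm**: 460 s runs at 39 Hz — 30 s lead-in, 16 task blocks
  (8 left / 8 right finger-opposition, first block left, at most 3 equal
  labels in a row) of 10 s separated by 15 s rests, 30 s tail.
- **Haemodynamics**: a double-gamma canonical HRF convolved with the task
  boxcar; Hb = −HbO/3; the response is lateralised to the pad contralateral
  to the moving hand with a spatial profile centred on a subject-specific
  locus.
- **Subject variability**: per-subject response amplitude, locus offset
  (`offset_sd_mm`, default 6.5 mm; larger values emulate poor or
  inconsistent cap placement) and systemic-physiology phases.
- **Nuisance signals**: Mayer waves (~0.1 Hz), respiration (~0.25 Hz) and
  cardiac pulsation (~1.1 Hz) common across channels, plus white measurement
  noise whose variance grows with separation (photon count falls
  exponentially with distance, so NN3 is noisiest).
- **FD forward model**: concentration changes modulate $\mu_a$; intensity
  follows $I = I_0 e^{-\Delta\mu_a L}$ and phase shifts linearly with
  $\Delta\mu_a$ via the diffusion-model phase sensitivity.
- **Artifacts**: `inject_bad_channels()` turns a chosen fraction of channels
  into high-variance garbage to exercise QC and interpolation; whole-run
  rejections are produced by contaminating more than 30 % of short channels.

The simulator does **not** model anatomy (no layered head, no partial-volume
effects), motion artifacts, optode-coupling drift, or scalp blood flow
separate from cerebral signal.  It is designed so that (a) every
preprocessing stage has something real to do, and (b) the spatial encoding
carries genuine class information that survives to the classifier.

## 4. Preprocessing chain

Per run, in order (`preprocess_run()`; all thresholds are
`preprocess_config()` fields):

1. **ΔOD / Δphase**: $\Delta OD = -\ln(I/\bar I)$ against the temporal mean
   (natural log; MBLL extinction terms carry the matching $\ln 10$ factor),
   phase minus its mean.
2. **Quality control** (`qc_flag()`): a channel is *poor* when its raw
   intensity coefficient of variation is **≥ 7.5** (boundary inclusive) at
   either wavelength; the run is *rejected* when **strictly more than 30 %**
   of short channels (< 30 mm) are poor.
3. **Interpolation**: poor channels in accepted runs are rebuilt as the mean
   of their good same-class Block neighbours (Chebyshev-adjacent voxels);
   no good neighbour is an error.
4. **Long-channel discard**: separations > 30 mm (NN3) are dropped.
5. **Band-pass**: 0.01–0.5 Hz 3rd-order Butterworth applied
   forward-backward (zero phase; ≥ 20 dB at 1.1 Hz, ≤ 1 dB at 0.1 Hz).
6. **MBLL** to HbO/Hb (or passthrough keeping OD/phase planes).
7. **Resample** 39 Hz → 2 Hz with a Blackman windowed-sinc anti-alias
   kernel normalised per output sample.
8. **Z-score** each series (population σ).
9. **Windowing**: one 20-frame (10 s) example per task block and per
   complete inter-block rest: 16 task + 15 rest = **31 examples per run**;
   33 accepted runs give the canonical **1023 examples**.

## 5. Classifiers

Both networks are trained by the same compiled engine (im2col + GEMM in
single precision, He initialisation, ReLU, inverted dropout, Adam on
softmax cross-entropy, deterministic given the seed):

- **3D CNN** on Block images: one convolution layer, 16 filters with
  temporal kernel 4 and spatial kernel 3 × 3 over all 6 layers, then two
  fully connected layers of 100 units with dropout 0.4, then softmax over
  {left, right, rest}.
- **1D CNN** on Flat matrices: 8 filters with temporal kernel 4 applied
  per row (no cross-channel mixing before the FC stage, verified by a
  row-permutation equivariance test), dropout 0.8, same FC head.

Defaults: batch 50, learning rate 0.01, 60 epochs.  On the synthetic
cohorts the loss plateaus within a few epochs, so the test-suite and the
acceptance script train for **4 epochs**; this is a budget choice, not a
tuned hyperparameter, and the exported defaults are unchanged.

## 6. Evaluation protocol

`make_splits()` offers two schemes, always splitting at session boundaries:
**mixed-subjects** (last run of every subject is the test set) and
**subject-independent** (leave-one-subject-out).  Mirror augmentation is
applied to Block *training* folds only; `flip_augment()` refuses test data.
Scores are **macro F1** over the three classes (a class absent from both
prediction and truth contributes 0, which penalises degenerate collapses).
`compare_stats()` reports per-cell Shapiro-Wilk normality, a balanced
two-way fixed-effects ANOVA (model + subject) on macro F1, and pairwise
post-hoc t-tests paired over (subject, repeat) with raw (uncorrected)
p-values; each statistic is validated against an explicit hand computation
in the tests.

## 7. Decisions on under-determined points

- **ΔOD log base**: natural log, with extinction coefficients scaled by
  $\ln 10$ inside the MBLL system so the inversion is base-consistent.
- **Z-score σ**: population (divide by $n$), so the output second moment is
  exactly 1.
- **Rest windows**: only the 15 complete inter-block rests are used (the
  lead-in/tail rests have different durations), giving 31 examples per run.
- **Flip axis**: the whole 33-column frame is reversed about the midline
  column, which the two-pad symmetry makes exact.
- **QC boundaries**: CV threshold inclusive (≥ 7.5 is poor), rejection
  fraction exclusive (> 30 % rejects), matching the stated boundary
  behaviour; both are config-overridable.
- **Pathlengths**: derived from the FD diffusion model per channel
  separation instead of a global DPF constant.
- **Optimiser**: Adam with the stated batch size/learning rate; the engine
  is hand-rolled because no deep-learning runtime is assumed at install
  time.

## 8. A small end-to-end run

```{r example, eval = FALSE}
co <- simulate_cohort_windows(n_subjects = 3, n_runs = 2, seed = 1)
blk <- to_block(co$windows, co$table)
res <- run_comparison(list("cnn3d+block" = blk),
                      scheme = "subject_independent",
                      n_repeats = 3, seed = 1, n_epochs = 4)
summarise_results(res)
compare_stats(res)
```

The repository-level `scripts/acceptance.R` runs the full protocol
(7 × 5 cohort, chance band, jittered-cohort model comparison) and writes
all computed quantities to JSON.
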