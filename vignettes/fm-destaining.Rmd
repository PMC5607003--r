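---
title: "Quantifying FM-dye destaining kinetics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying FM-dye destaining kinetics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fmdestain)
```

## The measurement

FM styryl dyes partition into recycling synaptic vesicle membranes; on
field stimulation, exocytosis releases the dye into the bath and each
presynaptic punctum's fluorescence decays. Time-lapse confocal imaging of a
labelled field therefore gives, per punctum, an *unloading curve* whose
decay rate reports vesicle release. This package quantifies two things from
such recordings:

1. **Responsiveness.** A punctum that loses more than 5% of its normalized
   fluorescence within 60 s of stimulation onset is *responsive*; the rest
   are *unresponsive*. The per-field percentage of responsive puncta
   measures the fraction of stimulus-coupled terminals.
2. **Decay constant.** For responsive puncta, the normalized trace from
   stimulation onset onwards is fitted with a single exponential with a
   free plateau,

   $$F(t) = C + A\,e^{-(t - t_\mathrm{stim})/\tau}, \qquad
     A \ge 0,\; C \ge 0,\; \tau > 0,$$

   by Levenberg–Marquardt least squares with box constraints
   (`minpack.lm::nls.lm`; starting values $A_0 = F(t_\mathrm{stim}) -
   F(t_\mathrm{end})$, $C_0 = F(t_\mathrm{end})$, $\tau_0 = 60$ s). The
   plateau is free because FM destaining rarely reaches zero — a
   non-releasable residual and any uncorrected background keep late-time
   fluorescence positive. Fits with $\tau$ above `tau_max_s` (default
   360 s) are flagged non-releasing and excluded from τ statistics; they
   are reported in a separate column, never silently merged into the
   unresponsive count.

## The image-processing chain

`run_analysis()` composes the stages in a fixed order: sum projection →
8-bit conversion → registration → (raw | background-subtracted branch) →
segmentation → mask assignment → traces → classification → fitting →
exclusion → summary.

* **Sum projection.** Per-pixel sum over the z axis, in double precision.
* **8-bit conversion.** The series-global range maps linearly to 0–255
  with `floor`; a constant series maps to zero. Conversion precedes
  registration (the order is recorded in the run log); since the map is
  global and monotone, the registration argmax and every threshold decision
  are unaffected by the order.
* **Registration.** Translation-only, integer-pixel: each frame receives
  the shift (within ±`search_radius`) that maximizes the zero-padded
  cross-correlation of mean-centred images with the reference frame, the
  last baseline frame by default. Mean-centring matters: with raw
  intensities the larger overlap at zero shift biases the correlation
  toward no correction. Shifted-in pixels are zero-filled. Subpixel or
  rotational motion is out of scope — stage drift over a 4-minute
  acquisition is well approximated by whole-pixel translation.
* **Background subtraction.** The frame whose time is nearest to
  stimulation onset + 180 s (ties to the later frame; at the default
  16-frame timeline this is the last frame) is subtracted from every frame,
  clamping negatives to zero — 8-bit data cannot represent them, and the
  segmentation threshold is positive.
* **Segmentation.** Foreground is `pixel ≥ 15` (inclusive) on the 8-bit
  frame; components are 8-connected; components outside 0.4–10 µm²
  (inclusive bounds; `area = n_pixels · pixel_size_um²`) are flagged
  out-of-gate and excluded from kinetics. ROIs are seeded once, from the
  first (pre-stimulation) frame, and reused across the series.
* **Colocalization.** The eGFP channel is thresholded by Otsu's
  bimodal-split method and dilated (default 2 px) to enclose spines; a
  punctum is on the outline iff its centroid pixel is inside the mask.
  Marker channels are segmented with the same punctum detector (own
  threshold); an FM punctum is marker-positive iff a marker-focus centroid
  falls within its pixels dilated by 1 px. Both criteria are deterministic
  and configurable; the dilation tolerances absorb sub-pixel misalignment
  between channels.

### Which branch feeds which statistic

Two registered branches run in parallel: the raw branch and the
background-subtracted branch. Classification always uses the raw branch.
Two further choices were genuinely open and are worth stating:

* **Segmentation uses the raw branch by default.** An unresponsive punctum
  has, by definition, the same intensity in every frame — including the
  background reference frame — so it cancels exactly in the subtracted
  branch and can never be detected there. Counting responsive *and*
  unresponsive puncta requires seeding ROIs where both are visible.
  `segment_on = "bgsub"` remains available for analyses restricted to
  destaining puncta.
* **Fitting uses the raw normalized trace by default.** The subtracted
  trace equals $A(1-r)\,[e^{-t'/\tau} - e^{-t'_\mathrm{ref}/\tau}]$: the
  reference frame removes not only background but the punctum's *own*
  late-time signal, leaving an effective negative plateau that the
  $C \ge 0$ constraint cannot absorb. Fitting the free-plateau exponential
  to such traces is badly biased (a true τ of 120 s fits near 68 s at the
  default timeline). On the raw normalized trace the model is exact — $C$
  absorbs background and the non-releasable residual — and recovery is
  unbiased. `fit_trace = "bgsub"` keeps the alternative available; a unit
  test documents its bias.

Boundary conventions are strict where the defining phrase is strict: the
responsiveness rule is evaluated as `normalized value < 0.95` (so exactly
5% unloading is unresponsive; comparing on the normalized scale keeps the
boundary exact in floating point), the intensity threshold is inclusive
(`≥ 15`), the area gate is inclusive on both ends, and the τ ceiling is
inclusive (`τ ≤ 360 s` kept). The frame "at 60 s" and "at 180 s" after
onset is the frame nearest that time, later frame on ties — at the default
15 s cadence both are exact. Frames are indexed 1-based; the time of frame
$k$ is $(k-1)\cdot$`frame_interval_s`.

## The simulator

`simulate_experiment()` generates the full acquisition the pipeline
expects: a T×Z×Y×X stack (default 4 baseline + 4 stimulation + 8
post-stimulation frames at 15 s; 31 z-slices; 192×192 px at 0.215 µm/px,
i.e. a 60× objective with 2×2 binning, making the 0.4–10 µm² gate a
realistic 9–216 pixels), an eGFP dendrite channel, optional marker
channels, and a truth table. Puncta are 2-D Gaussians (σ = 0.3 µm)
integrated per pixel; the z dimension spreads each spot across slices with
normalized weights, so sum projection recovers the 2-D model exactly.
Before noise and drift, a responsive punctum follows

$$I(t) = B + A\left[r + (1-r)\,e^{-\max(0,\,t - t_\mathrm{stim})/\tau}\right]$$

with per-punctum amplitude $A$, residual fraction $r \in [0.05, 0.2]$ and
decay constant τ; unresponsive puncta stay at $B + A$. True τ values are
lognormal; the default population (mean 124.8 s, sd 79.7 s) is an
uninjured-control-like condition, and `tau_preset()` provides the matching
axotomy-like population (mean 78.65 s, sd 68.4 s) whose faster unloading
reflects the higher release probability of injured-culture terminals.
Noise is per-voxel Poisson (shot) plus Gaussian read noise; drift is a
bounded integer random walk (≤ 1 px/frame, |cumulative| ≤ 6 px by default)
applied as whole-frame translation; optional global photobleaching is off
by default. Dendrites are piecewise-linear skeletons (reflected at field
edges) dilated to 2 µm with spine-like protrusions; a configurable
fraction of punctum centres lies on the mask.

Parameters the protocol does not pin down were fixed once at realistic
values and matter in one specific way: the fixed absolute threshold of
15/255 requires the summed background to stay well below ~6% of the
dynamic range, otherwise background pixels enter the foreground. The
defaults — punctum peak 600–1200 summed counts over 0.2 counts/slice
background with 0.5 counts read noise, typical of a 16-bit spinning-disk
camera — give peak SNR ≈ 25 and an 8-bit background of ~3. Punctum
centres keep ≥ 2 µm separation and a 12 px edge margin, so detected
components never merge and match radius 2 px identifies puncta uniquely.

**What the simulator does not emulate** — and hence what passing tests do
not certify on real data: spatially varying background and flat-field
error, out-of-focus haze and a realistic 3-D PSF, touching or overlapping
puncta (no watershed splitting is implemented), subpixel and rotational
stage motion, stimulation-electrode artefacts, and dye re-uptake or
photochemistry beyond a single optional bleaching exponential.

## Statistics

`compare_tau()` is an unpaired two-tailed Welch *t*-test on per-punctum τ
with group means ± s.e.m.; its type-I error is verified at α = 0.05
against the binomial envelope over 500 null simulations.
`compare_curves()` deliberately replaces an omnibus repeated-measures
ANOVA with per-timepoint Welch tests Bonferroni-adjusted across
timepoints: the package's goal is stage-by-stage pipeline verification,
and the output carries a note saying exactly what was computed.
Degenerate inputs resolve deterministically (identical groups give
*t* = 0, *p* = 1).

## Verification strategy and problem sizes

Every image primitive with a simple definition (projection, 8-connected
labelling, windowed correlation registration, ROI-mean extraction) is
tested against an independent brute-force oracle on randomized fixtures;
the exponential fitter against noiseless traces (τ from 30 to 300 s,
recovery within 0.5%) and a grid-search oracle. End-to-end recovery runs
20 default-condition fields (40 puncta each, noise and drift on): median
relative τ error stays under 5%, classification accuracy above 95%, and
segmentation precision/recall at 1.0 against truth centres (2 px match
radius). The discrimination experiment runs 100 seed pairs of the
control-like vs axotomy-like presets, one 100-punctum field per condition
(3 z-slices to keep a seed pair under ~3 s), requiring a Welch *p* < 0.05
in ≥ 95% of pairs. These sizes keep the whole suite around four minutes on
one CPU while leaving each statistical check enough resolution to fail
loudly if a stage regresses.

Numerical edge cases are handled explicitly rather than by accident: a
constant series maps to all-zero 8-bit output; a zero or negative
normalization reference excludes the punctum with a reason code instead of
dividing; flat traces yield no τ (`converged = FALSE`, reason
`"no_decay"`); registration ties break deterministically (smallest
|dy|+|dx|, then dy, then dx); and the degenerate Welch cases are pinned.

## Known limitations

Beyond the simulator gaps above: the fitter assumes mono-exponential
destaining (no multi-exponential or kiss-and-run models); segmentation has
no splitting of touching puncta; registration is integer-pixel
translation only; marker colocalization uses a centroid-in-dilated-ROI
criterion rather than object-overlap statistics; and the per-timepoint
curve comparison does not model within-punctum correlation across time, so
its p-values are conservative descriptions of pointwise separation, not an
omnibus test.
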