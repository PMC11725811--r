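---
title: "Models and methods behind metquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind metquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

metquant packages the quantitative procedures used to characterize
mechanoelectrical transduction (MET) in cochlear hair cells: patch-clamp
trace analysis, sub-pixel hair-bundle motion tracking with stiffness
estimation, ratiometric confocal quantification, and gene-set overlap
arithmetic for the downstream transcriptomic comparisons. Every analysis
stage has a matching synthetic-data generator with exact ground truth, so
the whole pipeline is testable end to end without any raw recordings. This
vignette explains the underlying models, the defaults, and the choices that
were genuinely open.

## The MET channel model and trace analysis

The generator treats the bundle's MET channels as a population of
`n_channels` identical two-state channels with single-channel conductance
`g_single` and reversal potential `e_rev` (near 0 mV, as expected for a
nonselective cation channel). Open probability follows a single Boltzmann
of bundle displacement $x$:

$$P_{open}(x) = \frac{1}{1 + e^{-(x - x_{set})/\lambda}},$$

with gating slope $\lambda$ (`lambda_slope`, default 20 nm). No channel
model is uniquely dictated by the recordings being emulated; the single
Boltzmann is the minimal form that reproduces a tunable resting open
probability, which is all the analysis code needs to be exercised against.
Gating kinetics (fast/slow adaptation time constants) are deliberately out
of scope.

Ca^2+^ entering through open channels at rest drives adaptive channel
closure. We model this statically: the set point is shifted by
`adapt_gain * max(0, e_rev_ca - V)`, i.e. proportionally to the inward
Ca^2+^ driving force (with `e_rev_ca` fixed at +40 mV). This reproduces two
well-established phenomena without any kinetics: resting open probability
rises toward positive potentials, and suppressing Ca^2+^-dependent
adaptation with a fast buffer (the `BAPTA_5mM` label zeroes the shift)
raises the resting open probability relative to the slow-buffer (`EGTA_1mM`)
condition. `p_rest` parameterizes the *unadapted* resting open probability
(the value under strong BAPTA buffering, or at potentials at or above
`e_rev_ca`); `x_half` is derived from it by inverting the Boltzmann at the
resting position. The default `adapt_gain` of 0.3 nm/mV makes the EGTA
resting open probability at −84 mV about 0.13 when the unadapted value is
0.5, typical of outer hair cells.

The fluid-jet stimulus is a driver voltage (DV) waveform — by default a
50 Hz sinusoid delivered across a membrane-potential series from −124 mV to
+96 mV (20 mV increments from −84 mV) — converted to force by a linear gain
`dv_gain` (default 100 nN/V) after first-order low-pass filtering
(`tau_jet`, default 0.5 ms). The true jet calibration procedure is
rig-specific; the linear gain is a configuration constant, flagged as such.
The bundle itself is an overdamped Hookean spring,
$c\,\dot x = F - k x$, so a force step settles at $x = F/k$; with $k$ in
mN/m and $F$ in pN, $x$ comes out in nm (1 mN/m = 1 pN/nm). Sign
conventions throughout: positive DV and positive displacement are
excitatory (toward the tallest stereocilia row); inward current is
negative.

The analysis side never sees the model. `cycle_average()` detects the
stimulus period from the driver autocorrelation and folds the current into
one mean cycle. `peak_to_peak_current()` takes the extrema of the averaged
cycle in the excitatory and inhibitory half-phases (defined by driver
sign, with DV = 0 in neither phase) and reports
`i_max = i_exc - i_inhib`, signed. "Maximal MET current" is read as this
peak-to-peak (excitatory-minus-inhibitory) quantity: that reading makes a
resting open probability of exactly 1 attainable. The resting open
probability is then

$$P_{open} = \frac{I_{hold} - I_{inhib}}{I_{max}},$$

with the holding current averaged over the annotated stimulus-off baseline
(first 10 ms when unannotated). The raw value is reported unclamped, with a
quality flag outside [−0.05, 1.05], and the whole estimate is flagged
unreliable when `|i_max|` is below 5 baseline-noise SDs — a resting open
probability is meaningless once the MET current is gone. Both thresholds
are arguments.

`build_iv_and_reversal()` interpolates the reversal potential linearly
between the two voltages bracketing the zero crossing of the signed
peak-to-peak I–V curve, and reports it absent (never extrapolated) when
there is no sign change. `detect_saturation()` declares a
gradually-increased stimulus series saturated when the last increment grows
the current by less than 5% — the protocol it mirrors specifies only
"until the maximal current was achieved", so the 5% figure is a documented,
configurable choice.

## Bundle tracking and stiffness

A movie frame images the bundle edge as a Gaussian line profile; a
kymograph is the frame-by-frame reslice along the measurement line.
Profiles are min–max normalized per frame (the normalization is invariant
to camera gain and offset, and fitted amplitudes are therefore reported in
normalized units) and fitted with a Gaussian amplitude function
`offset + A exp(-(p - c)^2 / (2 s^2))` by Levenberg–Marquardt least
squares, initialized at the intensity-weighted centroid with a 2-pixel
width. Failures are flagged, not raised: solver failure, a centre outside
the profile support, or a collapsed width (< 0.5 pixel). Tracking reports
positions relative to the mean pre-stimulus centre; a trace with more than
20% failed frames is flagged unusable. Noise-free localization bias is
below 0.02 pixel across sub-pixel offsets, and shot-noise precision is
within a factor of two of a dense grid-search maximum-likelihood reference
(in practice within a few percent of it).

Stiffness is the lumped Hookean estimate `k = F / x_steady`, with
`x_steady` averaged over the final 20% of the force step — the plateau, by
which time the mechanics (settling time `c_drag/k`, default well under a
millisecond) have settled; the step must outlast about five settling
times. The "apparent overall" steady-state stiffness deliberately lumps
series compliances and any geometric lever arm into one constant: the force
on the bundle is taken to equal the calibrated jet force. A plateau
displacement indistinguishable from zero (under 3 pre-stimulus SDs) leaves
`k` undefined with a flag; a zero-force step is an error.

## Ratiometric confocal quantification

MYO7A immunofluorescence is quantified relative to F-actin (phalloidin) in
anisotropic Gaussian volumes centred at five anatomical landmarks along the
hair cell: stereocilia tips, stereocilia bases, cuticular plate, and apical
and basal cytoplasm. The kernel SDs are fixed per landmark — 250 nm (x–y)
and 500 nm (z) at the stereocilia positions, 1 µm/500 nm at the cuticular
plate, 1 µm/1 µm in the cytoplasm — and asserted as defaults in the test
suite. Weights are truncated at ±4 SD per axis (and at the stack boundary)
then renormalized to sum exactly 1, so a constant field always averages to
itself; the truncation radius is an argument. Both channels are averaged
with the identical weight field and the ratio of the weighted averages is
the measurement. The denominator has a floor (1% of the actin channel
maximum, configurable): below it the ratio would be noise-dominated and the
measurement is flagged invalid instead. Background subtraction is off by
default. Landmarks are supplied as annotations (JSON), not auto-detected.

Group summaries aggregate cells into mean ± SD (sample SD) per genotype,
age and landmark, and the knockout effect is reported as
`100 (1 - mean_ko / mean_control)` per landmark — both the per-landmark
values and their range are available, since a published range can be read
either way.

The synthetic stack assigns each voxel to the compartment of its nearest
landmark (piecewise-constant actin level and MYO7A/actin ratio plus
Gaussian noise). Default landmark depths sit 4 µm apart along a 22-µm
cell, so the stereocilia kernels (σ~z~ = 500 nm) sample their compartments
essentially exactly, while the 1-µm cytoplasmic kernels mix a few percent
of the neighbouring compartment when compartments differ strongly. That
mixing cancels exactly in control/knockout comparisons with a uniform
reduction factor, which is the configuration used for the recovery checks;
it is a known limitation for absolute per-landmark ratios on strongly
non-uniform cells.

## Gene-set overlap arithmetic

Differential-expression tables are filtered with the standard thresholds
|log2FC| > 0.5, lfcSE < 0.5, adjusted p < 0.01 — all strict inequalities,
with the fold-change threshold applied to the magnitude, since both up- and
downregulated genes are reported downstream (whether the original analysis
applied it signed is not stated; magnitude is implemented and flagged
here). Rows with missing adjusted p-values are excluded and counted.
Identifiers are normalized by trimming and case-folding only; no ortholog
or symbol mapping. Percentages are reported both raw and rounded half-up,
because published percentages are rounded inconsistently (e.g. 1,007/3,266
printed as 30%). The differential-expression fit itself (e.g. DESeq2) is
out of scope: only its declared thresholds and the downstream set
arithmetic are implemented.

The synthetic gene universe allocates identifiers to named sets with
specified pairwise overlaps (one pair at a time, so no triple
intersections) and emits full-universe tables whose rows pass the
thresholds exactly when the gene belongs to the contrast's set.
`fig_overlap_spec()` encodes the published maturation/knockout structure:
3,266 maturation DEGs, 1,739 knockout DEGs at P30 with 1,007 shared (all
downregulated in the knockout, 713 of them upregulated during maturation),
and a 64-gene hair-bundle panel with 16 knockout DEGs, 14 of them down.

## Two-group statistics

`compare_groups()` offers Welch's t test (delegated to `stats::t.test`)
and the Mann–Whitney U test. For combined n ≤ 20 the Mann–Whitney p-value
is exact: every assignment of the pooled observations is enumerated, ties
handled through midranks, and the two-sided p-value is the proportion of
assignments whose U deviates from its null mean n₁n₂/2 at least as far as
observed. (This symmetric-deviation definition gives p = 1 for identical
groups and 2/252 for complete separation at 5 vs 5.) Larger samples use
the normal approximation with tie correction and no continuity correction,
cross-checked against `stats::wilcox.test`. The published analyses' omnibus
two-way ANOVA/Šídák machinery is deliberately delegated to standard
routines and not re-derived; this package implements the two-group tests
and summaries its own pipelines need.

## Reproducibility and problem sizes

All randomness flows through explicit integer seeds; generators save and
restore the caller's RNG state. `run_pipeline()` executes
generator → analysis → summary for every configured stage, writes
per-stage CSVs and a JSON manifest (configuration, seeds, package version,
per-stage status), and is byte-identical on rerun with the same
configuration and seed; stages fail independently.

The recovery studies use the study-condition sizes throughout: 50-kHz
traces with ten 50-Hz stimulus cycles per voltage; 900-frame movies at
5 kHz with 50-nm pixels; 96×96×88-voxel stacks at 50×50×250 nm; a
20,000-gene universe; 20 seeded replicates per condition. A worked example
with the numbers these settings produce is in the README.
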