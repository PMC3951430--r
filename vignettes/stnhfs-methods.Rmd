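---
title: "Methods: the stnhfs analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the stnhfs analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`stnhfs` implements the quantitative analysis stages of a chronic
subthalamic high-frequency stimulation (STN-HFS) experiment in the
bilateral 6-OHDA rat model of Parkinson's disease: an intra-animal
consensus screen for stimulation-regulated genes on probe-level microarray
data, counter-regulation detection against the lesion effect, open-field
locomotion segmentation, LFP/ECoG band-power statistics, optical
fractionator stereology, and ΔΔCT / densitometric validation.  Raw animal
data of this kind are rarely deposited, so the package ships a
synthetic-data module that generates every input with recorded ground
truth; all stages are validated by recovering what was planted.

# The consensus expression screen

## Model

Probe-level chip intensities are treated as log2-additive:

    log2 I(g, p, s) = mu_g + a_{g,p} + u_{g,animal(s)} + e(g, s) + effects

with gene baseline `mu_g`, probe affinity `a`, a per-animal random effect
`u`, and residual noise `e`.  The screen never fits this model explicitly;
it is the justification for the intra-animal design: comparing the
stimulated against the non-stimulated hemisphere of the *same* animal
cancels `mu`, `a` and `u` exactly, including any global state of the
animal (circadian phase, vigilance, handling) that an across-animal
design would absorb as noise.

Preprocessing follows the robust multiarray averaging recipe: quantile
normalization across samples (via `limma::normalizeQuantiles`), Tukey
median polish per probe set for summarization, and optional trimmed-mean
scaling to a target of 300 for intensity-scale reporting.  Background
correction is deliberately omitted by default: the synthetic data carry no
optical background, and no background parameters are available to match.
A flag-gated stub documents the omission.

## Change calls and signal-log ratios

For each comparison (one experiment chip vs one baseline chip) a probe set
receives a ternary change call from a paired test on its per-probe log2
differences.  The default test is the paired t-test; an exact Wilcoxon
signed-rank variant is selectable (`method = "signed-rank"`), which is the
natural nonparametric counterpart and is exactly enumerable at the chip
family's 11 probes per set.  The decision threshold `gamma` is 0.0025 per
direction (the magnitude documented for the vendor's change algorithm) and
is compared against the two-sided p as `p < 2 * gamma`, so that No Change
is equivalent to `p` at or above the two-sided threshold.  Zero variance
with zero difference yields No Change at `p = 1`.

The signal-log ratio (slr, the log2 fold change) defaults to the
difference of median-polish summary signals; a Tukey-biweight location
(`c = 5`, `epsilon = 1e-4`) of per-probe log2 ratios is available as
`method = "probe-ratio"`.  Both are antisymmetric under swapping baseline
and experiment.

## Comparison plans and the consensus rule

For two animals per group the stimulation contrast uses the classic four
comparisons: two intra-animal (stim vs non-stim of the same animal) and
two cross-comparisons (stim of one animal vs non-stim of the other); for
k animals this generalizes to k intra + k(k-1) cross pairs.  The lesion
contrast pairs every lesioned non-stim chip against every control
non-stim chip.

A probe set enters a regulation list when it shows homonymous calls (all
Increase or all Decrease) in at least `required_count` comparisons
(default: all four, the strict rule) *and* passes the slr gate of ±0.6 —
the log2 of a 1.5-fold change — in every counted comparison individually,
not merely on average.  `mean_slr` averages over the counted comparisons.
Genes measured by several probe sets are reported per probe set; no
gene-level collapsing is attempted.

Counter-regulation is declared when a gene in the stimulation list has a
lesion-effect homonymous count of at least `lesion_min_count` (default 3,
matching the observed range of lesion supports) with the opposite slr
sign.  Enrichment of annotation terms is scored by the EASE statistic:
the hypergeometric upper tail evaluated after removing one hit
(`max(k - 1, 0)`), reported as `-log10(p)` with `p` clamped to
`[1e-300, 1]`; the jackknife makes single-hit terms unscorable by design.

## What the generator emulates — and what it does not

`gen_expression_dataset` plants three gene classes: stimulation-down
(negative slr on lesioned-stim chips), lesion-up (positive slr on all
lesioned chips, so the intra-animal stimulation contrast stays clean),
and counter-regulated genes belonging to both.  Planted magnitudes are
uniform on [1, 2.8] (stimulation) and [1, 1.9] (lesion), the span of the
regulation lists this design produces.  Noise defaults — animal effect SD
0.1, hemisphere effect SD 0.05, probe noise SD 0.25, probe affinity SD 1,
all log2 units — were chosen once so that the consensus screen has high
power at planted |slr| ≥ 1 while cross-comparisons still carry visible
animal-to-animal noise; no probe-level noise magnitudes are published for
this design.  The generator does not emulate optical background,
PM/MM probe pairs, spatial chip artifacts, or circadian co-regulation
(the design argument for the intra-animal contrast, not a data feature).
Passing truth-recovery tests therefore demonstrates correctness of the
screen's logic, not robustness to every chip pathology.

# Locomotion

Speed is the net displacement across a centred 0.3 s window divided by the
window span; edge windows shrink symmetrically (the two endpoint samples
use a one-step window).  Rest and motion episodes are runs below/above the
4 cm/s noise level; runs shorter than `min_duration` (default 0.5 s) are
merged into their longer neighbour, shortest first, so labels always
alternate and episodes partition the recording.

Per motion episode the pipeline computes "max-SD".  The name suggests a
speed derivative but the quantity is reported in cm/s at speed-like
magnitudes (group means of 17–20 cm/s), so the default is the maximal
smoothed speed within the episode; a central-difference
maximal-|dv/dt| variant is available behind `variant = "max-derivative"`.
The natural-log max-SD values over all motion episodes form a bimodal
distribution; a Gaussian KDE (Silverman bandwidth) identifies the two
highest local maxima and places the full-motion threshold at the deepest
minimum between them.  Two guards keep degenerate inputs honest: candidate
modes must reach 5 % of the main peak, and the valley must dip below 80 %
of the smaller peak — otherwise the result is flagged single-mode rather
than silently thresholded.

"Spatial spread" is implemented as the cumulative path length over
full-motion episodes: the published magnitudes (81–142 m over 23 h) are
path-like rather than extent-like.  A convex-extent variant was considered
and rejected as the default because no arena-bounded extent can reach
those values; the choice is logged in every run summary.

The track generator schedules alternating rest/motion episodes.  Motion
bouts run at a constant plateau speed with one-sample onsets
(`ramp_frac = 0`): acceleration is fast relative to the 12.8 Hz sampling,
and keeping every motion step above the noise level makes zero-jitter
truth recovery exact — bout counts, per-bout peak speeds and path lengths
are reproduced to machine precision, because segmentation can only extend
an episode into zero-length rest steps, never trim moving ones.  Near
arena walls the heading steers smoothly toward the centre (≤ 0.45 rad per
sample) instead of reflecting, so instantaneous speed never collapses
mid-bout.  Rest jitter is drawn in a 0.25 cm disc, bounding rest-phase
windowed speeds below 2 cm/s by construction.  The generator does not
emulate thigmotaxis, grooming micro-movements, or tracking dropouts.

# Field-potential spectra

Channels are re-referenced by bipolar derivation where appropriate, notch
filtered at 50 Hz (second-order IIR biquad, Q = 30, applied
forward–backward over mirror-padded data for zero phase), and converted to
power spectral densities by Welch's method: 2 s Hann segments with 50 %
overlap, giving 0.5 Hz resolution — fine enough to resolve the 1 Hz band
edges.  PSDs are normalized to total power in 1–80 Hz; band powers sum the
normalized bins inside seven inclusive bands (delta 1–3, theta 4–7, alpha
8–12, low beta 13–24, high beta 25–35, low gamma 36–49, high gamma
51–80 Hz).  The 50 Hz bin is excluded from every band sum, mirroring the
gap between the gamma bands.  For displays, time–frequency power is
multiplied by frequency and column-normalized, which turns an exact 1/f
spectrum into a flat one.

Group comparisons use the exact Wilcoxon rank-sum test per band with a
Bonferroni threshold of 0.05/7 ≈ 0.007.  With six channels per group the
test is in its exact regime; complete separation yields
p = 2/924 ≈ 0.0022.

The signal generator produces spectrally shaped Gaussian noise
(1/f^exponent), an optional sinusoid at 32 Hz (the high-beta peak of the
parkinsonian state) and an optional 50 Hz line component.  Per-channel
exponents emulate electrode-to-electrode background variability; this is
what lets the band screen be selective (only the planted band flagged)
rather than trivially flagging every band through the normalization
coupling.  Real LFP features not emulated: non-stationarity, movement
artifacts, phase–amplitude coupling, and broadband shifts with vigilance.

# Stereology

The optical fractionator design is parameterized by counting frame
(50×50 μm), dissector height (20 μm), sampling grid (150×150 μm), section
thickness (40 μm) and sampling period (3), giving the canonical dissector
volume of 50000 μm³ on a 22500 μm² grid cell.  Density is total count
over total sampled volume, converted to cells/mm³; it is the primary
output (rather than total number) because the sampled volume deliberately
covers only part of the structure.  Volume uses the Cavalieri estimator
(period × thickness × summed areas), with ROI areas taken from the input
table.  The per-animal sampling period is an input column, not a
constant, since section availability varied between animals.

The coefficient of error offers two estimators: the Poisson "noise" term
1/√ΣQ, and a section-series estimator adding the Gundersen–Jensen
systematic-sampling variance (smoothness class m ∈ {0, 1}; Gundersen et
al. 1999, J Microsc 193:199–211), with the variance term floored at zero.
For smooth count series the systematic term is small and the estimate
approaches the noise term from above; strongly alternating series inflate
it, which the tests exercise directly.  Poisson resampling confirms the
noise CE tracks the empirical CV within 20 %.

# Validation assays

ΔΔCT: per animal and condition, ΔCT is the replicate-aggregated target CT
minus the reference (Rpl13A-style housekeeping) CT; ΔΔCT subtracts the
baseline condition and the slr is its negative — one PCR cycle per log2
unit.  The baseline condition must be named explicitly in every call;
leaving it implicit invites silent sign errors.  Replicates aggregate by
mean (median behind a flag; no published outlier rule exists for the
triplicates).  Group tests pool replicate-level ΔCT values across animals
in a fixed-effect rank-sum comparison with a Bonferroni family of seven
genes; hemispheres are not modelled as random effects, matching the
fixed-effect analysis described for this design.  Densitometric slrs
normalize band density by the lane's loading control before the log2
ratio, cancelling lane-wide exposure scaling.

# Numerical conventions

* Median polish: at most 10 sweeps or largest removed median < 1e-8;
  medians use R's midpoint convention for ties.  The batch implementation
  sweeps all probe sets simultaneously and is oracle-checked against
  `stats::medpolish`.
* Rank-sum: exact (via the closed-form null distribution) iff combined
  n ≤ 12 and tie-free, two-sided by doubling the smaller tail, capped at
  1; otherwise midranks with tie-corrected normal approximation and no
  continuity correction, so identical groups give exactly p = 1.
* EASE p clamped to [1e-300, 1].
* Intensities floored at 1e-3 after exponentiation so logs stay defined.
* All randomness flows from one run seed; each generator derives its own
  stream as `seed + 7919 * stage_index` (stages numbered: expression 1,
  locomotion 2, signals 3, stereology 4, qPCR 5), so any stage can be
  regenerated independently and reruns are bit-identical.

# Problem sizes

The default synthetic chip experiment uses 5000 probe sets × 11 probes ×
8 samples — large enough that the consensus screen's sensitivity and
empirical false discovery are measured on hundreds of planted and
thousands of null genes, while a full screen completes in well under a
minute on one core.  The full chip complement (31043 probe sets) runs
unchanged via `n_probesets` if desired.  Spectral runs use 30–60 s of
1 kHz signal (≥ 29 Welch segments); locomotion runs 20–30 bouts;
stereology defaults to 6 sections × 100 sites.

# Known limitations

* The change-call algorithm is an open reimplementation of a closed
  vendor method: it mirrors the published description (paired tests on
  probe pairs, a per-direction threshold), not the vendor's bit-exact
  behaviour.
* The published analysis' exact change-call p thresholds are not stated;
  `gamma` is configurable and its default is the vendor-documented
  magnitude.
* The exact "second" coefficient-of-error formula is not reproduced in
  the source description; the implementation pins the published
  Gundersen–Jensen family instead and documents it.
* Sensitivity/FDR guarantees hold under the generator's noise model;
  real chip data with heavy-tailed probe noise or batch structure may
  behave differently.
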