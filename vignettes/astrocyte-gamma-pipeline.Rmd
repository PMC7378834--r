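---
title: "Methods: astrocyte territory segmentation, calcium events, and astrocyte-gamma coupling"
author: "gliawave"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: astrocyte territory segmentation, calcium events, and astrocyte-gamma coupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliawave)
```

`gliawave` analyses paired recordings of cortical astrocyte calcium (two-photon
imaging of a GCaMP6f-like activity channel alongside an SR101-like structural
channel) and electrocorticogram (ECoG) during peripheral electrical
stimulation. This vignette is the package's own account of the methods: the
models and rules each stage implements, the assumptions behind them, the
tunable parameters with their defaults and units, what the synthetic-data
generator does and does not emulate, and the numerical conventions. Nothing
here states an empirical result that the test suite does not itself compute.

## 1. Territory segmentation

Astrocyte morphology is taken from the structural channel only. The stages,
each exposed as a function and orchestrated by `segment_territories()`:

1. **Structural thresholding** (`threshold_structural`). SR101-positive
   pixels are those strictly above the `struct_threshold_quantile` (default
   0.90) of the image's intensity distribution. A high quantile keeps the
   morphology estimate conservative. Raising the quantile can only shrink
   the mask (tested as a monotonicity property).
2. **Background** (`estimate_background`): the mode of the intensity density
   outside the thresholded regions. The mode is robust against the bright
   somata that distort a mean or median.
3. **Center detection** (`detect_cell_centers`). Local maxima of the
   Gaussian-smoothed (`smooth_sigma` = 3 px) structural channel, kept if they
   stand above background by half the maximal prominence and are separated
   by at least 0.75 territory diameters. Explicit seed points — the manual
   workflow — bypass detection and snap to the local maximum within 3 px.
   Centers within `edge_margin` (12 px) of the border are flagged
   `edge_clipped`; flagged cells are kept but excluded from population
   statistics, as are cells overlapping a user-supplied vasculature mask
   (no automatic vessel detector is attempted).
4. **Polar transform** (`polar_transform`). Pixels are binned by rounded
   radius (step `radial_step` = 1 px) and by angle (`n_angular_bins` = 36);
   per radius the mean, median and SD of the circle of fluorescence are
   tabulated.
5. **Soma** (`delineate_soma`). The soma radius is the smallest radius at
   which the azimuthally averaged, background-subtracted fluorescence first
   falls below `soma_fraction` (default 0.50) of its central value, located
   by linear interpolation between radial bins; the mask is the disk of that
   radius. The 50 % reference level is the central (r = 0) azimuthal mean:
   for any monotone radial profile this gives a unique radius, and for a
   Gaussian profile of scale σ it equals σ√(2 ln 2) — the closed-form oracle
   the tests check at σ ∈ {3, 5, 8} px within 1 px. The azimuthal-average
   reading (rather than a per-angle soma boundary) is a deliberate choice;
   a per-angle variant would require a smoothing policy along angles that
   the rule itself does not supply.
6. **Arborization** (`delineate_arborization`). A pixel beyond the soma
   belongs to the arborization iff its intensity strictly exceeds
   median + `arb_k` × SD (default 0.25) of its radius circle, restricted to
   the connected component adjacent to the soma. Two conventions are
   deliberate: the threshold combines both circle statistics as
   "`arb_k` SDs above the median", and ties are excluded (strict `>`). Note
   a perfectly uniform circle can never strictly exceed its own median, so
   the rule presumes the arborization occupies a minority of each circle —
   true for process-bearing morphologies, and the regime the generator
   produces.
7. **Microdomains** (`grid_microdomains`). An axis-aligned grid of
   `microdomain_size` (3 µm) squares anchored at the cell center — anchoring
   at the center rather than the image origin makes microdomain identity
   translation-equivariant per cell. A grid square is a microdomain iff at
   least `min_microdomain_overlap` (0.5) of its area lies in the
   arborization; its pixel set is the intersection with the mask, so
   microdomains are pairwise disjoint.

Segmentation is equivariant to image translation and invariant to positive
rescaling of the structural channel (both tested exactly on noiseless
fields).

## 2. Calcium traces and events

`extract_traces()` averages the activity channel over each ROI's pixels:
one trace per soma, whole arborization, and microdomain. `compute_dff()`
normalizes to ΔF/F₀ with F₀ the mean fluorescence over the pre-stimulus
baseline window; detection on ΔF/F rather than raw fluorescence makes the
rule scale-free (multiplying the movie by any positive constant changes
nothing — tested).

`detect_events()` implements the 3-SD rule: threshold = baseline mean +
`k_sd` × baseline SD of ΔF/F (defaults: `k_sd` = 3; baseline = everything
before stimulus onset, at least 5 s). An event is a maximal contiguous
strictly supra-threshold excursion; excursions separated by less than
`min_separation` (1 s) merge (prevents noise-split double counting);
excursions shorter than `min_frames` (2 frames) are discarded. The
minimum-extent gate exists because the 3-SD threshold itself admits
single-frame noise crossings at the normal-tail rate of ≈ 0.00135 per frame
— calibrated exactly by the tests — which over a long responder window would
otherwise masquerade as low-rate events; genuine GCaMP6f transients span
many frames. The raw supra-threshold frame count is still reported
(attribute `n_supra_frames`) so the per-frame calibration remains
observable. On noiseless data the baseline SD vanishes and the threshold
falls back to a documented floor (`dff_floor` = 0.02 ΔF/F); with that floor
the pipeline recovers injected events exactly (count, and onsets within one
frame plus the floor-crossing time).

A ROI is a **responder** (`classify_responder`) iff an event peaks between
stimulus onset and offset + `response_grace` (10 s) — astrocyte responses
lag the stimulus by seconds, so a grace window after offset is required;
its length is exposed in the configuration. `population_response()` reports
the percentage of responding ROIs per compartment class over QC-passing
cells; `event_rate()` converts counts to events/min; `reliability()`
histograms per-ROI response counts over repeated identical trains.

## 3. Stimulus-response sigmoids

Population responses against stimulus duration (s), pulse frequency (Hz) or
intensity (mA) are fit to

$$R(x) = \frac{r_\mathrm{max}}{1 + e^{-r_\mathrm{slope}(x - r_{50})}} + r_\mathrm{min},$$

with $r_\mathrm{min}$ pinned to zero for calcium population responses and
freed for spectral band-power curves (whose baseline-relative floor need not
be zero). `fit_sigmoid()` uses a Levenberg–Marquardt minimizer with the
analytic Jacobian; optional 1/SEM² weights (unweighted by default — the
fitting procedure deliberately makes no assumption about the error structure
of 5–6-point curves). Initialization follows a secant heuristic:
$r_\mathrm{max}$ from the data range, $r_{50}$ at the point nearest
mid-range, $r_\mathrm{slope}$ from the steepest secant scaled by 4/range —
reliable for the small designs this method meets in practice.
$r_\mathrm{max}$ and $r_\mathrm{slope}$ are constrained non-negative
(responses are non-negative and non-decreasing in the stimulus); a fit
pinned at the slope bound, or one that stalls, returns `converged = FALSE`
rather than raising. The covariance is the Gauss–Newton estimate
$\hat\sigma^2 (J^\top J)^{-1}$; `confint()` uses t intervals on the residual
degrees of freedom. Tested properties: exact recovery (to 1e-4 relative) on
noiseless curves of both variants; reparametrization consistency under
rescaling of x; Monte-Carlo bias below half the sampling SD with 95 %
interval coverage inside [0.90, 0.99].

## 4. ECoG spectral chain

- `lowpass_fir()`: zero-phase windowed-sinc (Hamming) FIR lowpass at
  `lowpass_cutoff` (100 Hz), applied by FFT convolution with group-delay
  compensation and reflection padding. The tap count is sized from the
  Hamming transition-width rule so that ripple stays below 0.1 dB under
  0.8 × cutoff and attenuation exceeds 40 dB above 1.2 × cutoff (tested on
  tones, along with the zero-phase property).
- `spectrogram_db()`: sliding Hamming windows of `window_length` (4096
  samples; ≈ 2.44 Hz resolution at 10 kHz), hop = window × (1 −
  `overlap_fraction`); the default 75 % overlap gives ≈ 0.1 s updates,
  adequate for dynamics on the 20–60 s scale. One-sided power spectral
  density referenced to 1 mV²/Hz, in 10 log₁₀ dB, floored at `db_floor` so
  silence is finite. Absolute dB values are reference-dependent; every
  metric downstream uses dB *differences*, which are reference-free.
- `smooth_welch()`: Welch averaging applied along time — each output column
  is the mean (in linear power) of `welch_segments` (4) neighbouring
  periodograms, reducing per-bin variance by about the segment count. This
  reading — smoothing the temporal frequency dynamics, not collapsing to a
  single PSD — is what a spectrogram-based workflow needs.
- `band_power()`: mean dB over the bins of a half-open band [f_lo, f_hi).
  Defaults: low 0–1, delta 0–4, theta 4–7, alpha 8–12, beta 13–30, gamma
  30–50 Hz; low and delta overlap deliberately, reproducing the reference
  band table.
- `relative_power()`: power_db(t) minus the mean over a pre-stimulus
  baseline window (≥ 5 spectrogram windows; an error if it overlaps the
  stimulus).
- `gamma_metrics()`: peak = maximum relative gamma within
  `peak_search_window` (10 s) after onset (a maximum, with the window
  length configurable, rather than a short-window mean); steady state =
  mean relative gamma from `steady_state_start` (50 s) after onset to
  stimulus offset (undefined and flagged for shorter stimuli); ratio =
  100 × steady/peak, the astrocyte-dampening index, computed on
  relative-dB values.
- `detect_upstates()`: up-states are slow, large deflections. The signal is
  restricted below `upstate_env_cutoff` (10 Hz) — which also removes gamma
  oscillations — rectified, and smoothed into an envelope. Hysteresis
  thresholding (trigger at mean + 2 SD, extent at mean + 0.5 SD) avoids
  clipping the measured duration; accepted excursions must last 0.3–2.0 s
  and reach `upstate_min_amplitude` (0.1 mV). The detector is an invented
  formalization — reference up-state identification was by amplitude
  (0.17 ± 0.05 mV), duration (0.93 ± 0.10 s) and waveform — and all its
  parameters are config-exposed. The amplitude floor stands in for the
  waveform criterion: without it, slow excursions of a 1/f background pass
  the envelope threshold. Apply the detector to baseline epochs; a
  sustained stimulus response inflates its threshold.

## 5. Astrocyte-gamma coupling

`align_streams()` interpolates both series linearly onto a uniform 0.5 s
grid over their overlap (≥ 20 s). `pearson_with_t()` computes Pearson r and
the two-sided p from $t = r\sqrt{(n-2)/(1-r^2)}$ — checked against both a
brute-force formula and `stats::cor.test` to 1e-12, and calibrated under the
uncoupled null (uniform p-values). Population calcium is summarized as mean
arborization ΔF/F by the pipeline; the percentage of active ROIs is an
equally valid summary for correlation-style analyses and can be supplied
instead. `cross_correlation_lag()` reports the signed lag (positive =
calcium follows gamma) of the maximal normalized cross-correlation of the
mean-removed streams within ±30 s.

**Hysteresis area.** The trajectory traced in the (calcium, gamma) plane
over stimulation and recovery encloses a loop when the two signals rise and
fall with a lag. `hysteresis_area()` is its shoelace (polygon) area, closed
by a straight chord between the endpoints (real trajectories do not return
exactly; the chord gap is reported), signed positive for the
gamma-rises-first orientation. The area is invariant to adding constants to
either stream and bilinear under separate rescalings (both tested). The
loop-area metric and its calibration are this package's formalization of a
phenomenon usually shown only graphically. The zero reference is a
surrogate null (`hysteresis_null_floor()`): circular time shifts of the
calcium stream — preserving marginals and autocorrelation while destroying
the alignment — with a minimum shift of 10 s so that surrogates cannot
trivially reproduce the original alignment, summarized by the 95th
percentile of |area|. One caution from the model's own structure: the loop
area is dominated by a stimulus-boxcar edge term (gamma level × calcium
excursion) that is present whenever calcium responds at all, independent of
the feedback gain; with the feedback present the aligned trajectory exceeds
every time-shifted surrogate, but in the gain-free world the observed area
sits at the edge of its own surrogate distribution rather than far below
it. The tests therefore phrase the gain-free contrast as a
majority-of-seeds statement, and the corner case of feedback with zero
delay is not claimed — in this generator the astrocyte delay is
constitutive.

`condition_compare()` reports group means ± SEM of peak, steady state and
ratio, with Welch t-tests delegated to `stats::t.test()`; ANOVA-style
analyses are likewise delegated to standard routines rather than
re-derived.

## 6. The synthetic world

The generator's defaults are the stated world; they were fixed once, from
printed reference values where those exist and from field-typical choices
where they do not, and the tests are run against them.

**Structural field** (`make_astrocyte_field`). Cells at random centers with
minimum separation 0.8 × territory diameter; each is a Gaussian soma
(σ = 4 µm, peak 100 a.u.) plus `n_arms` = 6 radial processes with a
super-Gaussian (quartic) cross-section of scale 1.5 µm, amplitude 60 a.u.
decaying with radius, ramping on just outside the soma, truncated at the
territory radius (20 µm); background 10 a.u., pixel noise SD 3 (soma SNR
~33, process SNR ~20 — representative of averaged SR101 stacks). The
quartic cross-section gives processes a sharply defined footprint, so
"where the process is" is well-posed; ground truth marks pixels whose
noiseless process signal exceeds twice the pixel noise (resolvable
structure). Field 192 px at 0.6 µm/px.

**Calcium movies** (`simulate_calcium_movie`). Each compartment (soma, each
ground-truth microdomain) is an independent Bernoulli responder with
probability equal to the product of the per-dimension response sigmoids,
each normalized by its own maximum — the reference experiments vary one
stimulus parameter at a time, leaving the joint dependence unspecified, and
the normalized product preserves each marginal shape. Default triplets
(r_max %, r_50, r_slope): duration (82.8, 7.5 s, 0.4 s⁻¹), frequency
(91.8, 1.7 Hz, 1.9 Hz⁻¹), intensity (91.7, 1.7 mA, 2.0 mA⁻¹). Responders
receive one transient at onset + delay, delay ~ Normal(4 s, 1 s) truncated
at zero (a "several seconds" delayed response), kernel
(1 − e^{−t/1.5 s}) e^{−t/4 s}, ΔF/F amplitude uniform in [0.4, 1.2] —
far above the trace noise, so injected events are detectable by
construction. Spontaneous events arrive at `basal_rate` (1/min, the
reference basal arborization rate) with a 12 s dead time that keeps
injected events resolvable as separate excursions. The whole-arborization
ROI aggregates its microdomains, so its responder probability is emergent
(near 1 when many microdomains respond) rather than sigmoid-calibrated;
calibration statements are made at the microdomain level. Note that
spontaneous events are genuine responder contamination for evoked-response
calibration — a ROI with a spontaneous event inside the response window
counts as a responder, exactly as in real data — so the sigmoid-recovery
tests run with `basal_rate = 0`.

**Feedback loop** (`simulate_feedback`). A phenomenological discrete-time
model (Δt ≤ 0.1 s): with S(t) the stimulus indicator,

$$C_{t+\Delta t} = C_t + \Delta t\,(\alpha\, S(t-\delta)\, G_t - C_t/\tau_c),
\qquad
G_t = g_\mathrm{peak}\, S(t)\, (1 - k\, C_t / C_\mathrm{ref}) + \varepsilon_t,$$

gamma in relative dB, calcium in relative units. α is fixed at
1/(τ_c g_peak) so that without feedback C saturates at C_ref = 1; the
closed-form steady-state/peak ratio is then 1/(1 + k·drive). Defaults:
g_peak = 14.7 dB (the reference peak), k = 0.61 (wildtype ratio
1/1.61 = 62.1 %), δ = 4 s, τ_c = 6 s (seconds-scale population calcium
decay; together with δ this puts the gamma-to-calcium lag at
δ + ln2·τ_c/(1+k) ≈ 6.6 s). `ip3r2_ko` mode scales the calcium drive by
0.42 (ratio 1/(1+0.61·0.42) = 79.6 %) and, in the movie generator, scales
response probabilities toward the reported near-abolition; `dreadd_cno`
mode adds 0.5 units of tonic calcium (shifting gamma responses down) and
multiplies the basal event rate by 3.5. No functional form for the
gamma decline during sustained stimulation is given by the reference
observations; the linear-feedback form here is one admissible choice and
all contrasts built on it are directional, not quantitative claims about
real tissue.

**ECoG** (`simulate_ecog`). 10 kHz samples = pink (1/f, flattened below
0.5 Hz) background scaled to `pink_rms` (0.04 mV) + Poisson up-states
(rate 0.1 Hz; amplitude Normal(0.17, 0.05) mV floored at 0.1; duration
Normal(0.93, 0.10) s clamped to [0.3, 2]; half-sine waveform) + a gamma
comb: four tones placed exactly on the analysis spectrogram's FFT bin grid
(bins 13/15/17/19 of fs/4096 = 31.7/36.6/41.5/46.4 Hz), each of baseline
amplitude 0.05 mV, amplitude-modulated as 10^(envelope dB/20). On-bin
tones plus their one-bin Hamming leakage drive every 30–50 Hz bin, all
band bins scale together with the envelope, and the measured band dB
(a mean of per-bin dB values) tracks the envelope analytically — a single
off-grid carrier would move only the bins it occupies and the band mean
would under-read the envelope by the carrier-bin fraction. This
construction makes band-power targets controllable by design; it does not
claim spectral realism of gamma (real gamma is broadband).

**What a green test does not establish.** The generator has no motion,
no photobleaching, no neuropil contamination, no vessel shadows, no
z-drift; its noise is Gaussian and white; its astrocytes are radially
symmetric apart from discrete processes; gamma is a deterministic comb.
Passing tests validate the *analysis chain* — that each rule recovers what
it is defined to recover on data with the assumed statistical structure —
not performance on real recordings.

## 7. Numerical conventions and edge cases

- One global seed; every stage derives its own stream via a deterministic
  hash (`gliawave:::child_seed`), so full pipeline runs are byte-identical
  under a fixed seed (tested).
- Strict `>` at both segmentation thresholds; ties excluded.
- The soma crossing radius is interpolated linearly between 1-px radial
  bins; profiles that never cross are rejected as non-cells.
- Noiseless traces: detection threshold floored at `dff_floor` (0.02 ΔF/F).
- Zero spectral power floored at `db_floor` (1e-20 mV²/Hz) before log.
- Degenerate (collinear) hysteresis trajectories return area 0 with a
  warning; the endpoint chord gap is always reported.
- TIFF movies are written as uncompressed little-endian 32-bit float pages
  (structural/activity interleaved) with a JSON sidecar carrying frame
  interval, pixel size and channel order; the reader is validated against
  an independent TIFF implementation. Configuration documents are JSON.
- All tables are CSV with a stable column order; scalar results JSON; label
  masks plain-text PGM.

## 8. Known limitations

- Single focal plane only; no 3-D segmentation, no motion correction, no
  vessel detection (vasculature exclusion is by user-supplied mask).
- No spike inference or deconvolution on calcium traces; no subcellular
  propagation analysis.
- Absolute spectral dB values are reference-dependent and not meaningful
  across rigs; only relative (baseline-subtracted) quantities are.
- The grand-mean curve is fit by default; per-group fitting is available by
  calling `fit_sigmoid()` per group, but no mixed-effects machinery is
  provided.
- The feedback model is phenomenological (no conductances, no IP3 receptor
  kinetics); its mode contrasts reproduce directions, not magnitudes, of
  loss- and gain-of-function manipulations.
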