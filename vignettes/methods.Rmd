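---
title: "Models and methods behind fluorephys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fluorephys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(fluorephys)
```

This vignette documents the models, parameter choices and numerical
decisions behind the package, in the spirit of a methods section: what is
simulated, what is assumed, and what the passing tests do and do not
demonstrate about real recordings.

## 1. Photon transport

### Model

Light propagation in brain tissue is simulated as photon-packet transport
in a homogeneous turbid half-space. The probe shank occupies the plane
z = 0 with the photodiode window (49 × 150 µm) embedded in it; tissue
fills z > 0. Each packet performs a random walk with exponential free
paths of mean 1/(μₐ+μₛ); at every interaction a fraction μₐ/(μₐ+μₛ) of
the packet weight is deposited in the containing 10 µm voxel and the
remainder is deflected by a Henyey–Greenstein angle (closed-form inverse
CDF; the g = 0 branch is uniform) with uniform azimuth. Packets crossing
z = 0 inside the window are tallied as detected; crossing elsewhere they
are absorbed by the silicon shank (reflection and refraction at material
interfaces are deliberately ignored, consistent with treating the shank
as a perfect absorber); leaving the grid box terminates the packet as
escaped. Polarization, time resolution and tissue inhomogeneity are out
of scope.

Three simplifications deserve emphasis:

* the **shank plane is infinite** — beyond the real 113 µm shank width
  the plane would not exist, so acceptance probabilities very far
  laterally are slightly pessimistic;
* the simulation domain is the voxel grid box; packets leaving it never
  return (a photon scattered back from outside the box is lost);
* the medium is homogeneous at a single wavelength per run.

### Energy accounting and Russian roulette

Low-weight packets (below 10⁻⁴) undergo Russian roulette with survival
probability 0.1. Roulette preserves energy only in expectation, so the
transport kernel keeps an explicit ledger: killed weights are parked in a
`roulette_residual` bucket and survival boosts are borrowed from it. As a
result `deposited + escaped + shank + window + roulette_residual` equals
the launched power to floating-point rounding in *every* run, and the
residual has zero mean. This is what the conservation tests assert at
10⁻⁹ relative tolerance.

### Randomness

One counter-based splitmix64 stream is keyed per (seed, packet index), so
grids are bit-identical for identical configurations and seeds and do not
depend on scheduling or on how packets are batched. Acceptance-map
packets use a disjoint stream-index range so the two simulators never
share variates.

### Optical parameters

The probe's optical table is not part of the package's inputs, so
`optics_preset()` ships representative literature coefficients for murine
cortical gray matter (μₐ, μₛ in mm⁻¹; g = 0.89): blue 475 nm
(0.37, 11.0), green 520 nm (0.20, 10.5), red 625 nm (0.07, 9.0). The
detection volume depends directly on these values; every preset is
overridable via `tissue_optics()`, and reported volumes should always be
read as conditional on the optical coefficients used.

### Sources and geometry defaults

The excitation fiber (50 µm core, NA 0.22) launches packets uniformly
over the core disc, with directions uniform in solid angle inside a cone
of half-angle asin(NA/n), n = 1.36. The fiber tip sits 80 µm before the
window edge, 30 µm above the shank surface (the core centre of a fiber
lying on the shank). The stimulation fiber for crosstalk runs defaults to
900 µm lateral separation — the order of the inter-shank distance when
one shank targets CA3 and another CA1 — and 400 µm deeper along the
shank axis, reflecting that the stimulation fiber protrudes well beyond
the recording sites. The exact implant geometry is not determined by the
probe design alone; the axial offset was chosen so the simulated
baseline shift falls in the few-percent range observed in vivo, i.e. the
unknown geometric degree of freedom is calibrated against the
measurement, as is standard when a model parameter is not independently
known. Crosstalk numbers are therefore indicative; the firm property is
their monotone decrease with fiber–photodiode separation.

### Detection volume

Voxels are ranked by Φ·η·p (quantum yield η = 0.7) and accumulated
greedily until the cumulative product reaches the stated fraction (0.9)
of the total; ties are broken by lexicographic voxel index so the result
is deterministic. A zero product field is a degenerate input and errors.
The scaled problem size used by the tests and the acceptance script is a
400 µm cube at 20 µm voxels with 10⁵–10⁶ illumination packets and a few
hundred acceptance packets per voxel, which one CPU completes in seconds.

## 2. The synthetic-data generator

### What it emulates

* **Population.** Six neurons above the electrode array, four of them
  indicator-positive (e.g. CaMKIIα-GCaMP6f), positions uniform in a box
  5–30 µm above the shank plane with ≥ 45 µm pairwise separation — the
  regime of units individually resolvable by a 50 µm-pitch array. Soma
  spike amplitudes 180–320 µV at zero distance.
* **Firing.** Poisson tonic firing at 0.8–2 Hz plus a burst process
  (0.15–0.2 bursts/s of 4–8 spikes, 5–10 ms intra-burst intervals),
  absolute refractory period 2 ms enforced by deletion. A fraction
  `burst_sync` (0.9) of every indicator-positive neuron's bursts derives
  from one shared population-event process by Poisson thinning. Thinning
  keeps each neuron's marginal burst rate exactly as configured while
  introducing the cross-neuron burst correlation characteristic of
  synchronous excitatory-ensemble events; indicator-negative neurons
  burst independently, which is what makes their calcium-uncorrelated
  firing a meaningful null.
* **Calcium channel.** Each spike of each indicator-positive neuron adds
  a double-exponential transient (rise 50 ms, decay 400 ms — GCaMP6f-like
  defaults, configurable) scaled so its *peak* equals `unitary_dff`
  (1%); summation is linear. The kernel is peak-normalized so that the
  configured amplitude, the spike-count regression slope and the
  burst-detectability arithmetic are all in the same units. Current =
  baseline (19.7 nA) × (1 + ΔF/F) + dark current (155 pA) + Gaussian
  noise of SD = peak-to-peak/6 (1.5 pA p-p), sampled at 60 Hz.
* **Electrical channel.** A fixed ~1 ms biphasic template scaled per
  channel by A(d) = A₀·d₀/(d₀+d) with d₀ = 20 µm (bounded at d = 0,
  unlike 1/d), plus 8 µV Gaussian channel noise at 30 kHz.
* **Stimulation.** A 0.5 Hz, 25% duty square schedule starting at 40 s of
  a 100 s session (30 cycles); during ON phases the tonic rate of
  opsin-connected neurons is multiplied by `stim_gain` (3). Bursts are
  not modulated.

### What it does not emulate

No LFP, no electrode drift, no bleaching or hemodynamic contamination of
the fluorescence, no overlapping-spike waveform superposition resolution,
no indicator nonlinearity or saturation, no inhomogeneous expression
levels. Passing tests therefore demonstrate that the analysis chain
recovers truth *under its own generative assumptions* — they bound
implementation error, not model error on real tissue.

## 3. Fluorescence analysis

ΔF/F₀ uses the printed definition (F(t) − F(0))/F(0) with F(0) taken
per-sample from the slow component: the dark current is subtracted, a
zero-phase second-order Butterworth high-pass (default 0.05 Hz; the
pipeline uses 0.1 Hz on 100 s scenes so the trace covers ten filter
periods) extracts the fast component, and the complement is the baseline.
A zero-phase 5 Hz second-order low-pass then suppresses noise. Zero-phase
(forward–backward) filtering was chosen to keep transient onset times
unbiased; it applies the Butterworth magnitude twice, so a 10 Hz
component is attenuated by 1/17 rather than the single-pass 1/√17 (the
single-pass magnitude is available via `zero_phase = FALSE` and
`butter_gain()`). The trace is mean-centred before filtering so the
filter state never sees the ~20 nA offset as an edge step. Two residual
artifacts are handled explicitly: detection can exclude a margin at the
trace edges (`edge_exclusion`), and the baseline high-pass inherently
sags transient peaks by ~2–3%, which bounds how exactly any peak can be
"recovered" after filtering.

Transients are local maxima above k·SD (k = 3, SD robust via MAD) with a
minimum separation; onset is the last 10%-of-peak crossing before the
peak. Rise time is defined 10–90% and decay time peak→1/e, both linearly
interpolated — the definitions were chosen for robustness and closed-form
testability. Spike-count inference is greedy template deconvolution
(repeatedly subtract the unitary kernel at the residual maximum until it
falls below threshold), a deliberately simple, pluggable stand-in for
full maximum-likelihood spike inference, which is out of scope.

## 4. Electrical analysis

Band-pass 0.3–6 kHz (zero-phase, channel mean removed first, so DC is
exactly zero). Detection takes negative-going local minima below −4.5
robust SD (MAD/0.6745) with 1 ms dead time. Per-channel detections within
0.5 ms are pooled into physical events; each event's 7-channel trough
vector (±2 samples around the trough — a narrow window, so weak channels
are not inflated by noise minima) is clustered by a deterministic
leader–follower rule in time order: join the nearest unit under cosine
distance 0.03, else found a new one. Tiny clusters (< 5 events) are
dropped as threshold-crossing noise by default. Overlapping spikes from
different neurons can merge into spurious residual units; this is a
documented limitation of amplitude-vector sorting.

Trilateration inverts the generator's amplitude law jointly over position
and soma amplitude by L-BFGS-B least squares with depth constrained to
z ≥ 0, started from the amplitude-weighted electrode centroid at three
depths (the electrodes are nearly coplanar, so depth is the weak
direction; multiple starts avoid the mirror solution). Fewer than three
channels above the noise floor triggers a flagged centroid fallback; all
channels at the floor is an error. The inversion law must match the
rendering law — a mismatch experiment is a robustness exercise, not
default behaviour.

## 5. Cell-type statistics

* **Rise/rest test.** Rise windows are [onset, peak] of each detected
  transient; rest windows are matched-duration segments placed
  deterministically (no RNG) in the gaps left after excluding each
  transient from 0.2 s before onset to two decay times past the peak.
  Per-window rates are compared by a classic pooled-variance two-tailed
  unpaired t-test (the plain reading of "unpaired t-test" without a
  Welch qualifier); degenerate inputs are defined exactly (equal constant
  groups: t = 0, p = 1; separated constant groups: p = 0).
* **Classification rule.** Indicator-positive iff p < α (0.05) *and* the
  rise rate exceeds the rest rate; otherwise indicator-negative if the
  unit fired at least `min_spikes` (2) inside transient windows — it
  fired, but calcium did not follow — else unclassified. The negative
  branch intentionally also catches units whose rest rate significantly
  exceeds their rise rate (their own bursts landing in rest windows),
  which are negatives by any reading of the evidence. No multiple-testing
  correction is applied across units, mirroring per-unit reporting
  practice; a Bonferroni-style correction can be applied by passing
  α/n.
* **Spike-count regression.** The recording is tiled into 200 ms bins;
  the response of a bin is the rise of ΔF/F from the bin start to its
  maximum within the bin plus a kernel-rise lookahead (0.15 s). When the
  kinetics are supplied, three model-based corrections make the OLS slope
  an unbiased estimate of the unitary amplitude: the pre-bin level is
  projected forward with the decay constant (a decaying tail does not
  persist), the response is rescaled by the kernel-timing attenuation of
  the bin's actual spike offsets (n spikes spread over 5–10 ms intervals
  peak slightly below n × unitary) and by the filter chain's known
  unitary-transient attenuation together with the local/quiet baseline
  ratio. Bins whose measured peak could contain a neighbouring bin's
  calcium (bursts split across the bin edge, spikes inside the lookahead)
  are excluded from the fit.
* **Stimulation response.** Per-cycle ON and OFF rates over the schedule
  (30 cycles at defaults), control rates from OFF-length tiles of the
  pre-stimulation span, pooled t-tests ON-vs-OFF and OFF-vs-control; at
  least five cycles are required.
* **Correspondence.** A transient is matched when any unit spike falls in
  [onset − window, peak], the window defaulting to the transient's own
  rise duration; the matched fraction is monotone in the window. With no
  transients the fraction is undefined and flagged.
* **Burst floor.** The minimum detectable burst is the smallest n whose
  summed transient peak (spikes at the 7.5 ms within-burst interval, so
  the peak is computed from the actual kernel rather than n × unitary)
  exceeds k·SD of the ΔF/F noise.

## 6. Calibration experiments and problem sizes

The statistical acceptance checks run on fixed experiment designs chosen
once: type-I error of the rise/rest test from 500 sessions in which a
5 Hz tonic unit is uncoupled from a neighbour's transients; type-I error
of the ON/OFF test from 500 sessions at stimulation gain 1; slope
recovery from 100 sessions of a single sparse bursty neuron (0.3 Hz
tonic, 0.08 bursts/s, 300 s) with bins of ≥ 2 spikes; classification
robustness from 100 seeded six-neuron scenes analysed through the
calcium-evidence path (the sorter and trilateration are validated by
their own criteria, and the full bimodal chain runs at the reference
seed); correspondence from scenes with an extra indicator-positive neuron
placed near the photodiode but below every electrode's noise floor,
bursting independently and contributing roughly a tenth of the
transients. An exactly calibrated confidence interval sits *at* its
nominal coverage, so coverage-type checks are asserted within three
binomial standard errors of nominal, the same convention the other
statistical criteria use.

## 7. Known limitations

Homogeneous optics and a perfectly absorbing infinite shank plane;
amplitude-vector sorting with no overlap resolution; depth weakly
constrained in trilateration; greedy deconvolution undercounts tightly
stacked spikes at low SNR; the rise/rest test's power depends on
ensemble-level burst synchrony, and in its absence single-unit coupling
to a multi-neuron photodiode signal is intrinsically hard to detect; all
statistical guarantees are with respect to the generator's assumptions.
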