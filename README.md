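# fluorephys

Simulation and analysis toolkit for **bimodal fluorescence + extracellular
electrophysiology neural probes**: implanted silicon shanks that carry a
photodiode (reading population calcium fluorescence from genetically
encoded indicators such as GCaMP6f) directly underneath a seven-electrode
array (reading single-unit spikes at 30 kHz). The central scientific
question such probes answer is *cell-type identification of sorted units*:
which extracellular units belong to the indicator-expressing
(e.g. CaMKIIα⁺, excitatory) population? A unit is indicator-positive when
its firing correlates with the photodiode calcium signal; it is
indicator-negative when it fires but the calcium signal does not follow.

The package is written for systems-neuroscience and neural-engineering
groups who design such probes or analyze their recordings, and it covers
both sides of the problem:

**Probe optics (photon-transport Monte Carlo).** Photon packets are traced
through turbid tissue with Henyey–Greenstein scattering (anisotropy *g*),
absorption *μₐ* and scattering *μₛ* coefficients, depositing energy in
10 µm voxels. Two maps are combined:

- the illumination fluence Φ(x, y, z) from the 50 µm excitation fiber, and
- the photodiode acceptance probability p(x, y, z) (fraction of isotropic
  emission from each voxel crossing the 49 × 150 µm photodiode window),

and the **fluorescence detection volume** is the smallest set of voxels
supplying 90% of Σ Φ·η·p (η the fluorophore quantum yield, 0.7), built by
greedy accumulation of the largest products. The same transport code
yields the red stimulation-light crosstalk on the photodiode baseline.
Analytic helpers cover the excitation-filter blocking ratio, the
transimpedance noise-equivalent current, and accelerated-aging lifetime
projection (2^(ΔT/10) per 10 °C).

**Bimodal signal analysis.** The 60 Hz photodiode current is converted to
ΔF/F₀ = (F(t) − F(0))/F(0) with a second-order Butterworth baseline
high-pass (0.05–0.1 Hz) and a 5 Hz smoothing low-pass; calcium transients
are detected, their 10–90% rise and 1/e decay times measured, and spike
counts inferred by greedy unitary-template deconvolution. The 30 kHz
electrode channels are band-passed 0.3–6 kHz, spikes detected at −4.5
robust SD, sorted by deterministic leader–follower clustering of their
7-channel amplitude vectors, and each unit localized by trilateration —
inverting the amplitude–distance law A(d) = A₀·d₀/(d₀+d) against the
electrode coordinates. Classification rests on a two-tailed unpaired
t-test of per-window firing rates during calcium **rise** versus **rest**
windows, supported by OLS regression of calcium change on 200 ms spike
counts and by ON/OFF firing statistics under periodic optogenetic
stimulation (0.5 Hz, 25% duty).

**Synthetic data.** Because such recordings are rarely shared, a seeded
generator produces ground-truth populations and fully rendered bimodal
sessions (Poisson tonic firing, synchronized ensemble bursts,
GCaMP6f-like transients summing linearly, 19.7 nA baseline / 155 pA dark /
1.5 pA p-p photodiode noise, amplitude-decaying spike waveforms across the
50 µm-pitch array), so every stage of the pipeline is testable against
known truth.

## Worked example

```r
library(fluorephys)

## optics: detection volume on a scaled grid (400 um cube, 20 um voxels)
geo  <- probe_geometry()
grid <- grid_spec(extent = 400, voxel_edge = 20)
flu  <- simulate_illumination(geo, optics_preset("blue475"), grid,
                              n_packets = 2e5, power = 0.3, seed = 1)
acc  <- simulate_acceptance(geo, optics_preset("green520"), grid,
                            n_packets_per_voxel = 200, seed = 2)
detection_volume(flu, acc, quantum_yield = 0.7, fraction = 0.9)
#> <detection_volume_result> 1.224e+06 um^3 (153 voxels, 90% of detected fluorescence)

## bimodal pipeline: generate a 6-neuron scene, analyse both channels,
## classify every sorted unit
res <- run_pipeline(seed = 1)
res$analysis$calls_table[, c("unit", "label", "n_spikes", "snr",
                             "rate_rise", "rate_rest", "p_rise_rest")]
#>   unit              label n_spikes   snr rate_rise rate_rest p_rise_rest
#> 1    1 indicator_negative      286  7.23      4.25     5.500    8.29e-01
#> 2    2 indicator_negative      239  4.87      4.87     3.612    6.30e-01
#> 3    3 indicator_positive      227  7.59     27.35     1.342    1.56e-07
#> 4    4 indicator_positive      140  7.01     12.08     0.556    4.29e-03
#> 5    5 indicator_positive      194  8.30     23.22     1.634    4.68e-07
#> 6    6 indicator_positive      240  8.25     24.53     1.356    3.99e-05
#> 7    7 indicator_positive       13 18.18      3.03     0.000    3.33e-03
res$accuracy
#> [1] 1
```

The detection volume is the tissue region contributing 90% of everything
the photodiode sees — about 1.2 × 10⁶ µm³ here, i.e. a shallow dome a few
tens of micrometres above the window. In the session table, units 3–6
fire significantly faster during calcium rises (p ≪ 0.05, rates in Hz)
and are called indicator-positive; units 1–2 fire heavily while calcium
stays flat and are called negative. Matched against the generator's
ground truth (four indicator-positive neurons among six), every matched
unit is labeled correctly (`accuracy` = 1); unit 7 is a small residual
cluster of overlapping-spike events. Per-unit SNR is the mean-waveform
trough over three times the channel noise SD.

Sessions can be persisted as plain-text containers (`write_session()` /
`read_session()`, bit-exact round trip), and
`inst/scripts/run_pipeline.R` wraps `run_pipeline()` for shell use
(`--config scene.yaml --seed S --out DIR`).

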