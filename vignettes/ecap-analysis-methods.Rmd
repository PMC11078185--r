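---
title: "Methods: evoked-potential analysis for circumferential spinal cord recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evoked-potential analysis for circumferential spinal cord recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecaptools)
```

## The problem

A thin-film electrode array wrapped fully around the spinal cord records
epidural potentials at many angular positions simultaneously. Evoked
compound action potentials (ECAPs) — time-locked positive waveforms
following a stimulus — then carry a *spatial* signature: somatosensory
volleys travel in the dorsal columns and project dorsally, while motor
volleys travel in the lateral and ventrolateral white matter and project
as a two-lobed lateral/ventrolateral pattern, mirrored between left and
right. `ecaptools` implements the full analysis chain for such
recordings: artifact removal, wavelet denoising and spike detection,
circumferential topographic mapping, source classification, a closed-loop
injury-bypass simulation, and spinal-cord circularity morphometry —
together with a synthetic-session generator that provides ground truth
for every stage.

Angle convention, used everywhere: 0° at the dorsal midline, increasing
toward the animal's left viewed from rostral, so +90° is left lateral and
±180° the ventral midline. Units are fixed: microvolts, seconds, Hz,
degrees.

## The synthetic-session generator

No recordings ship with the package; every analysis runs on sessions from
`simulate_session()`, whose defaults encode the reference acquisition
protocol: 70-s sessions of alternating left/right MEP/SSEP stimulation at
a 1-s inter-stimulus interval (70 events), 32 electrodes evenly covering
the circumference (11.25° spacing, one electrode on the dorsal midline),
sampled at 30 kHz.

Each source is an angular gain profile: a mixture of von Mises bumps
$g(\theta) \propto \sum_b a_b \exp\{\kappa_b(\cos(\theta-\theta_b)-1)\}$,
normalized to a maximum of 1. The von Mises shape was chosen because it
is the natural smooth unimodal density on the circle and has exactly two
interpretable parameters (centre, concentration). Defaults: SSEP left at
+25° with $\kappa = 8$ (a dorsal, side-shifted hotspot); MEP left with
bumps at +90° (lateral) and +140° (ventrolateral), $\kappa = 12$,
relative amplitudes 0.8/1.0; right-side sources are exact mirrors through
0°; tibial (+15°) and peroneal (+45°) are dorsal SSEP sub-sources close
enough to be non-trivial to separate. The concentrations put the
half-width of a hotspot at roughly 2–3 electrode spacings, which matches
how localized the reported topographies look while keeping adjacent
channels informative.

The ECAP template is a difference of Gaussians, $e^{-t^2/2\sigma_1^2} -
(\sigma_1/\sigma_2)\,e^{-t^2/2\sigma_2^2}$ with $\sigma_1 = 0.4$ ms and
$\sigma_2 = 1.2$ ms, sampled on the 4-ms analysis window and normalized
to a unit positive peak. It is biphasic with a dominant positive phase;
the scaling makes the untruncated integral zero (the 4-ms truncation
leaves a small residual). The conduction latency from stimulus to peak
defaults to 1.5 ms — a plausible cord-conduction figure at these
distances and, deliberately, a free configuration parameter: the
recovery tests check that the pipeline reproduces whatever value the
generator used.

Noise terms, added independently of the event schedule so that sessions
sharing a seed share a noise realization: a 6-Hz train of Ricker-shaped
QRS-like transients (rat heart rate) of 5-ms central-lobe width and 30 µV
amplitude, shared across channels; a 1-Hz, 20-µV respiration sinusoid; a
50-Hz, 10-µV mains sinusoid; independent white instrument noise of 10 µV
SD per channel; and a 100-µV, 0.5-ms biphasic stimulation artifact at
each event time. With the 50-µV hotspot amplitude this puts the peak SNR
at 5. What the generator does *not* emulate: volume-conductor effects
(channel-dependent artifact waveshapes), electrode impedance drift,
movement artifacts, latency jitter, amplitude adaptation over a train,
or unit activity. Passing tests therefore show that the chain recovers
its own model family under realistic amplitudes — not that it handles
every pathology of real recordings.

## Preprocessing

Active channels are referenced to "dormant" counterparts — electrodes
that carry no evoked response — to cancel shared artifacts (ECG,
respiration, stimulation transients). The default scheme subtracts the
*mean* of the dormant set, which halves the added reference noise
relative to a single-electrode reference. With the default sources
nothing projects near the ventral midline, so `ventral_channels()`
(|angle| ≥ 160°) is the default dormant set; which electrodes are dormant
is in general a required configuration choice, because it depends on the
stimulation protocol. Reference channels are passed through unchanged and
are excluded from spike detection — they still contain the artifacts that
referencing removed elsewhere.

The 50-Hz notch is a second-order constrained biquad (Q = 30, about
1.7-Hz bandwidth) applied forward–backward (`signal::filtfilt`), i.e.
zero-phase, because the latency analyses cannot tolerate a phase shift.
Epochs are half-open windows `[t - pre, t + post)`; the default analysis
window is 0 to +20 ms post-stimulus, and events whose window leaves the
recording are dropped with a warning rather than an error.

## Wavelet denoising and detection

Denoising is a three-level multiresolution analysis with orthogonal
Daubechies-5 filters. Each detail band is hard-thresholded at its own
universal threshold
$$Th_l = \sigma_l \sqrt{2 \ln N_l}, \qquad
  \sigma_l = \mathrm{median}(|c_l|)/0.6745,$$
where $c_l$ are the band's coefficients, $N_l$ its length, and 0.6745 the
75th percentile of the standard normal distribution; the approximation
band is never thresholded. Hard thresholding keeps a coefficient only
when $|x| > Th$ strictly; the boundary case $|x| = Th$ maps to 0 (the
conservative reading of a rule whose two branches are both strict).

The transform is *stationary* (undecimated, à trous) by default: every
band then genuinely has the length of the input signal, the transform is
shift-invariant (no detection jitter from the decimation grid), and
reconstruction after zero-thresholding is exact to machine precision. A
decimated pyramid variant is kept for comparison; its bands halve per
level. Boundaries are handled by symmetric extension around a circular
core transform. Both variants are scale-equivariant by construction
($\sigma$ and $Th$ scale with the signal), which the tests verify.

Spikes are detected on the reconstructed signal as local maxima above the
universal threshold *of the denoised series itself* (its robust-σ times
$\sqrt{2\ln N}$). The choice of where σ comes from matters: after hard
thresholding, detail bands are sparse and the raw signal's noise estimate
would put the bar at ~5.4 raw-σ, above a peak-SNR-5 ECAP. The denoised
series retains only the approximation-band noise (≈ σ/√8 at three
levels), so its own universal threshold lands at ~1.9 raw-σ — safely
under the evoked peaks and safely over the residual noise maxima, which
is what the sensitivity/FDR acceptance checks confirm. Detection is
positive-peak only by default (ECAPs are time-locked positive waveforms);
a signed mode exists. Accepted peaks are thinned greedily, largest first,
with a 4-ms refractory, and a 4-ms waveform window centred on each peak
is extracted (zero-padded and flagged at recording edges). The cardiac
component is isolated separately by a continuous-wavelet correlation with
a Ricker kernel at a 5-ms scale — matched to the QRS-like transient width
— whose response maxima mark beat times.

## Topographic mapping

The per-event, per-channel peak amplitudes form the map substrate; one
row interpolates piecewise-linearly between adjacent electrodes on the
circle (wrapping only under full coverage) onto a 1° grid that always
contains the electrode angles, where the frame passes through the data
exactly. Linear interpolation was chosen because anything smoother is a
display choice, and linearity gives two useful guarantees: frames never
overshoot the data range, and hotspot recovery is exactly equivariant
under source rotation. Hotspots are the global frame maximum plus, for
motor sources, the best separated second local maximum at least 30° away
(about the lateral/ventrolateral separation scale); a flat frame yields a
flagged no-hotspot result. `temporal_evolution()` bins the epoch window
(event-averaged mean amplitude per bin) to show the activation locus
moving after the stimulus.

## Classification and clustering

Features are the peak-amplitude map binarized at each channel's mean
(strictly greater than; ties at the mean map to 0, so identical events
produce all-zero features). Classification is k-nearest-neighbour with
k = 1 under the city-block (L1) metric, after a stratified 60/40
train/test split — stratified because with ~17 events per class a plain
random split can starve a test class; the split is seeded and exactly
reproducible. Tie-breaks are fixed (majority, then smallest within-tie
distance sum, then lowest class index) so the classifier has no hidden
randomness and matches a brute-force nearest-neighbour oracle
identically. PCA (centred SVD) is the linear embedding; UMAP is available
through the optional `uwot` dependency, with a clear error pointing to
PCA when it is absent.

The unsupervised "k = 2 / k = 4" analysis is implemented as k-medoids
(PAM) under the same L1 metric — the closest defensible exemplar-based
reading — with k-means as the alternative; neither is claimed to be the
original's algorithm. Cluster-to-label agreement is scored after optimal
matching, computed by exhaustive permutation search, which at k ≤ 6 is
the exact Hungarian-assignment optimum.

## The closed-loop bypass simulation

The bypass records above an injury, detects the descending MEP by a
rising-edge threshold crossing on the (preprocessed) proximal hotspot
channel, and stimulates below the injury after a configurable loop
delay. The default scenario: 1.5-ms stimulus-to-proximal-peak latency,
1.0-ms natural distal segment (pre-injury response latency 2.5 ms),
0.1-ms electronic loop delay, 1.0-ms response latency to direct distal
stimulation, gain 10, and the threshold at 40% of the expected proximal
peak — on the rising edge, so the crossing precedes the peak. Triggering
uses the amplified signal but thresholds are stated in raw microvolts
times gain. Before the injury the distal segment responds naturally;
after it, only trigger-driven stimulation produces responses (threshold
above all peaks ⇒ paralysis model, flagged). Latencies are measured from
the synthesized distal stream by peak detection, not copied from the
schedule, so the pre-injury condition is a genuine recovery test of the
configured conduction latency. The pre/post comparison is a two-tailed t
test, paired by default (same preparation before and after); the
unpaired Welch variant is available since the original design is not
stated. The simulation checks parameter recovery and the *direction* of
the latency change; the absolute in vivo latencies are not reproducible
without the original recordings.

## Circularity morphometry

Sections are explicit polygon outlines (`animal,section,repeat,x_um,y_um`
CSV), not images: segmentation belongs to the imaging software. The index
is $4\pi \cdot \mathrm{area}/\mathrm{perimeter}^2$ — shoelace area,
closing-edge-inclusive perimeter — 1.0 for a circle, invariant under
rigid motion and scaling, and maximal for the circle among all simple
closed shapes. Polygonized circles sit slightly below 1, so analytic
tests use ≥ 10³ vertices with a 10⁻⁴-level tolerance. Simplicity
(non-self-intersection) is validated exhaustively for outlines up to 256
vertices and is the caller's responsibility beyond that (the pairwise
test is quadratic). Protocol aggregation: nine measurements per animal
(three sections × three repeats; fewer accepted with a warning), animal
means compared against an explicit control reference value by a
one-sample two-tailed t test with the 95% CI of the group mean — the
reference is an argument because no universal control value exists. A
marching-squares helper traces binary masks into outlines; its raw
pixel-edge walk measures city-block length, so two midpoint
corner-cutting passes are applied by default (a traced disc then scores
CI ≈ 0.95; the helper is for convenience, not precision).

The bundled `synthetic_outlines.csv` is a generated cohort — six
synthetic animals with elliptical deformation of graded severity over a
~600-µm cord radius, re-measurement jitter of 4 µm — whose animal means
(≈ 0.75–0.82) sit in the range reported for healthy rodent cords; it
exists to exercise the aggregation and test machinery, not to stand in
for tissue.

## Numerical choices and problem sizes

* Daubechies-5 filter coefficients are the standard published constants;
  the filter bank's orthonormality and conjugate-quadrature structure are
  asserted in tests.
* Zero-threshold reconstruction error is bounded at 10⁻⁶ of the signal
  range (measured: ~10⁻¹⁵).
* Degenerate inputs fail loudly and specifically: empty coefficient
  bands, N < 1, zero-area polygons, empty dormant sets, windows outside
  the recording, unknown event labels, non-monotone event times.
* Sampling rate: the acquisition default is 30 kHz; the bundled analyses,
  tests and the acceptance script run the same study conditions at
  10 kHz, a reduction the configuration explicitly supports. At 10 kHz
  one sample is 0.1 ms, the unit in which peak-time recovery is
  assessed. Detection recovery uses 20 sessions × 70 events; the bypass
  analysis 10 sessions of 20 s; the shuffle control 50 permutations.
* Every stochastic step draws from an explicit seed; identical
  configuration and seed give byte-identical sessions.

## Known limitations

* The generator's artifacts are shared across channels with equal gain by
  default, which mean-referencing cancels almost exactly; real arrays see
  channel-dependent artifact gains and will retain residuals.
* The stationary-transform denoiser assumes Gaussian stationary noise for
  its threshold calibration; strongly non-Gaussian interference (chewing,
  movement) is outside the model.
* Hotspot localization reports grid-resolution angles from linear
  interpolation; sub-spacing accuracy would need a model-based fit.
* The bypass simulation is a signal-level model: electrode
  electrochemistry, charge limits, and real-time hardware latencies are
  out of scope.
* `circularity()` trusts outlines beyond 256 vertices to be simple.
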