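# ecaptools

Analysis of evoked compound action potentials (ECAPs) recorded by
electrode arrays wrapped **around the circumference of the spinal cord**.
A circumferential array sees each evoked volley as an angular amplitude
pattern — somatosensory potentials project dorsally, motor potentials as
a lateral + ventrolateral pair, mirrored left/right — and this package
implements the full chain that turns raw multichannel epidural recordings
into those spatial signatures and decisions built on them:

* **Denoising & detection** — three-level stationary Daubechies-5
  multiresolution analysis with per-level universal hard thresholds
  (`Th_l = σ_l √(2 ln N_l)`, `σ_l = median(|c_l|)/0.6745`), spike
  detection on the reconstructed signal, 4-ms waveform windows, and
  Ricker-wavelet (5-ms scale) extraction of the cardiac component.
* **Preprocessing** — referencing of active channels to dormant
  counterparts, zero-phase 50-Hz notch, event-locked epoching.
* **Topographic mapping** — per-event peak-amplitude maps interpolated
  around the circumference, hotspot localization (single and dual), and
  post-stimulus temporal evolution.
* **Classification** — per-channel mean-threshold binarization,
  city-block k-nearest-neighbour (k = 1) with a stratified 60/40 split,
  PCA/UMAP embeddings, and unsupervised k-medoids clustering (k = 2/4).
* **Closed-loop bypass** — rising-edge threshold triggering of distal
  stimulation across a simulated cord injury, with per-event latency
  records and the paired pre/post t test.
* **Morphometry** — spinal-cord circularity index
  `CI = 4π·area/perimeter²` from section outlines, nine-measurement
  per-animal means, and the one-sample group test.

No recordings are bundled; a synthetic-session generator
(`simulate_session()`) reproduces the statistical structure the analyses
assume — von Mises angular hotspots, biphasic ECAP templates, ECG /
respiration / mains / white noise and stimulation artifacts on an
alternating 1-s stimulation schedule — and returns the ground truth that
every recovery test scores against.

## Worked example

```r
library(ecaptools)

cfg <- default_session_config(sample_rate = 10000)  # desk-scale rate
s   <- simulate_session(cfg, seed = 1)              # 70 events, 32 channels

feats <- session_features(s)        # notch -> reference -> denoise -> detect
detection_metrics(feats$spikes, s$truth, cfg$sample_rate)
#>   sensitivity         fdr peak_time_mae_samples n_events n_detections
#> 1           1 0.002680965                  0.23       70          373

classify_session(feats$map, feats$labels, seed = 1)
#> <knn_result> k = 1, cityblock metric
#> accuracy: 100.0%
#>         predicted
#> true     MEP_L MEP_R SSEP_L SSEP_R
#>   MEP_L      7     0      0      0
#>   MEP_R      0     7      0      0
#>   SSEP_L     0     0      7      0
#>   SSEP_R     0     0      0      7

fr <- build_topoframe(colMeans(feats$map[feats$labels == "MEP_L", ]),
                      s$recording$layout)
find_hotspot(fr, n_hotspots = 2)[c("angle_deg", "secondary_angle_deg")]
#> $angle_deg            [1] 135      # ventrolateral lobe
#> $secondary_angle_deg  [1] 90       # lateral lobe
```

Every event was detected (no false discoveries beyond 0.3%), peak times
are recovered to a quarter of a sample, the held-out test events classify
perfectly into the four sources, and the motor hotspot pair lands on the
generator's ventrolateral/lateral angles to within one electrode spacing
(11.25°).

The numbered scripts under `analysis/` run the same chain as a narrative
workflow — `01_simulate.R` through `06_circularity.R` — writing tables
under `results/` (simulated session and containers, detected spikes and
recovery metrics, per-source topographic frames and the rotation sweep,
the confusion matrix and clustering agreements, bypass latency records
and the paired comparison, circularity measurements and the group test).

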