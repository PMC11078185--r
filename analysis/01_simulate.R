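#!/usr/bin/env Rscript

# Generate one reference synthetic session — 70 s of alternating
# left/right MEP/SSEP stimulation at a 1-s inter-stimulus interval on a
# 32-electrode circumferential array — and write the recording container,
# the event table and the generator's ground truth under results/.
# Desk-scale sampling rate (10 kHz) keeps the artifacts small; pass a
# different rate below to regenerate at the 30-kHz acquisition rate.

library(ecaptools)

dir.create("results", showWarnings = FALSE)

cfg <- default_session_config(sample_rate = 10000, seed = 1L)
session <- simulate_session(cfg)

write_recording(session$recording, "results/session_seed1.rec")
write_events(session$events, "results/session_seed1_events.csv")
write.csv(session$truth, "results/session_seed1_truth.csv",
          row.names = FALSE)
write_config(list(sample_rate = cfg$sample_rate, duration_s = cfg$duration_s,
                  isi_s = cfg$isi_s, amplitude_uV = cfg$amplitude_uV,
                  latency_s = cfg$latency_s, seed = 1),
             "results/session_seed1_config.json")

cat(sprintf("simulated %d events over %.0f s at %g Hz on %d channels\n",
            nrow(session$events), duration_s(session$recording),
            cfg$sample_rate, nrow(session$recording$data)))
cat(sprintf("hotspot ECAP amplitude %g uV over a %g-uV white-noise floor (peak SNR %g)\n",
            cfg$amplitude_uV, cfg$noise$white_sigma_uV,
            cfg$amplitude_uV / cfg$noise$white_sigma_uV))
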