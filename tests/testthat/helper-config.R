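# Desk-scale session configurations used across the suite: the standard
# acquisition conditions (32 channels, 1-s ISI, peak SNR 5) at a reduced
# 10-kHz sampling rate, with short durations where a test does not need
# the full 70-s session.

desk_config <- function(duration_s = 70, ...) {
  default_session_config(sample_rate = 10000, duration_s = duration_s, ...)
}

noiseless_config <- function(duration_s = 5, ...) {
  desk_config(duration_s = duration_s,
              noise = noise_model(ecg_amplitude_uV = 0,
                                  resp_amplitude_uV = 0,
                                  line_amplitude_uV = 0,
                                  white_sigma_uV = 0,
                                  stim_artifact_amplitude_uV = 0),
              ...)
}
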