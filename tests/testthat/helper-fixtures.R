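# Shared fixtures built in code.

# Minimal measurement table: one participant, one device, explicit values.
make_records <- function(sao2, spo2, participant = "P01", device = "dev",
                         dt_s = 120) {
  n <- length(sao2)
  data.frame(
    participant_id = rep(participant, n),
    device = rep(device, n),
    plateau = seq_len(n),
    sample = rep(1L, n),
    time_s = seq(0L, by = as.integer(dt_s), length.out = n),
    petO2_mmHg = rep(45, n),
    sao2_pct = sao2,
    spo2_pct = spo2,
    phase = rep(1L, n),
    stringsAsFactors = FALSE
  )
}

# Noise-free identity device: reading equals the (rounded) truth.
identity_device <- function(...) {
  device_error_model(bias_at_full_sat = 0, bias_slope = 0, noise_sd = 0,
                     averaging_window = 0, missingness_base = 0,
                     missingness_low_sat_boost = 0, ...)
}

# Small deterministic study for pipeline tests (fast: 3 participants).
small_study <- function(seed = 11, device_models = default_device_models()) {
  generate_study_dataset(
    participants = default_participants()[1:3],
    device_models = device_models,
    seed = seed
  )
}
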