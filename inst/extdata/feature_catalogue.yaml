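# The default 44-feature catalogue: 11 statistics per stream for the
# 4 streams (accel/gyro x raw/first-difference magnitudes). Serialised
# so deployments can substitute their own catalogue; extraction is
# name-keyed and validates 44 unique names, 22 per modality.
features:
- name: accel_raw_mean
  modality: accel
  stream: raw
  domain: time
  statistic: mean
- name: accel_raw_min
  modality: accel
  stream: raw
  domain: time
  statistic: min
- name: accel_raw_max
  modality: accel
  stream: raw
  domain: time
  statistic: max
- name: accel_raw_kurtosis
  modality: accel
  stream: raw
  domain: time
  statistic: kurtosis
- name: accel_raw_zero_crossings
  modality: accel
  stream: raw
  domain: time
  statistic: zero_crossings
- name: accel_raw_signal_area
  modality: accel
  stream: raw
  domain: time
  statistic: signal_area
- name: accel_raw_spectral_entropy
  modality: accel
  stream: raw
  domain: frequency
  statistic: spectral_entropy
- name: accel_raw_spec_min
  modality: accel
  stream: raw
  domain: frequency
  statistic: spec_min
- name: accel_raw_spec_q1
  modality: accel
  stream: raw
  domain: frequency
  statistic: spec_q1
- name: accel_raw_spec_mean_crossings
  modality: accel
  stream: raw
  domain: frequency
  statistic: spec_mean_crossings
- name: accel_raw_spec_area
  modality: accel
  stream: raw
  domain: frequency
  statistic: spec_area
- name: accel_diff_mean
  modality: accel
  stream: difference
  domain: time
  statistic: mean
- name: accel_diff_min
  modality: accel
  stream: difference
  domain: time
  statistic: min
- name: accel_diff_max
  modality: accel
  stream: difference
  domain: time
  statistic: max
- name: accel_diff_kurtosis
  modality: accel
  stream: difference
  domain: time
  statistic: kurtosis
- name: accel_diff_zero_crossings
  modality: accel
  stream: difference
  domain: time
  statistic: zero_crossings
- name: accel_diff_signal_area
  modality: accel
  stream: difference
  domain: time
  statistic: signal_area
- name: accel_diff_spectral_entropy
  modality: accel
  stream: difference
  domain: frequency
  statistic: spectral_entropy
- name: accel_diff_spec_min
  modality: accel
  stream: difference
  domain: frequency
  statistic: spec_min
- name: accel_diff_spec_q1
  modality: accel
  stream: difference
  domain: frequency
  statistic: spec_q1
- name: accel_diff_spec_mean_crossings
  modality: accel
  stream: difference
  domain: frequency
  statistic: spec_mean_crossings
- name: accel_diff_spec_area
  modality: accel
  stream: difference
  domain: frequency
  statistic: spec_area
- name: gyro_raw_mean
  modality: gyro
  stream: raw
  domain: time
  statistic: mean
- name: gyro_raw_min
  modality: gyro
  stream: raw
  domain: time
  statistic: min
- name: gyro_raw_max
  modality: gyro
  stream: raw
  domain: time
  statistic: max
- name: gyro_raw_kurtosis
  modality: gyro
  stream: raw
  domain: time
  statistic: kurtosis
- name: gyro_raw_zero_crossings
  modality: gyro
  stream: raw
  domain: time
  statistic: zero_crossings
- name: gyro_raw_signal_area
  modality: gyro
  stream: raw
  domain: time
  statistic: signal_area
- name: gyro_raw_spectral_entropy
  modality: gyro
  stream: raw
  domain: frequency
  statistic: spectral_entropy
- name: gyro_raw_spec_min
  modality: gyro
  stream: raw
  domain: frequency
  statistic: spec_min
- name: gyro_raw_spec_q1
  modality: gyro
  stream: raw
  domain: frequency
  statistic: spec_q1
- name: gyro_raw_spec_mean_crossings
  modality: gyro
  stream: raw
  domain: frequency
  statistic: spec_mean_crossings
- name: gyro_raw_spec_area
  modality: gyro
  stream: raw
  domain: frequency
  statistic: spec_area
- name: gyro_diff_mean
  modality: gyro
  stream: difference
  domain: time
  statistic: mean
- name: gyro_diff_min
  modality: gyro
  stream: difference
  domain: time
  statistic: min
- name: gyro_diff_max
  modality: gyro
  stream: difference
  domain: time
  statistic: max
- name: gyro_diff_kurtosis
  modality: gyro
  stream: difference
  domain: time
  statistic: kurtosis
- name: gyro_diff_zero_crossings
  modality: gyro
  stream: difference
  domain: time
  statistic: zero_crossings
- name: gyro_diff_signal_area
  modality: gyro
  stream: difference
  domain: time
  statistic: signal_area
- name: gyro_diff_spectral_entropy
  modality: gyro
  stream: difference
  domain: frequency
  statistic: spectral_entropy
- name: gyro_diff_spec_min
  modality: gyro
  stream: difference
  domain: frequency
  statistic: spec_min
- name: gyro_diff_spec_q1
  modality: gyro
  stream: difference
  domain: frequency
  statistic: spec_q1
- name: gyro_diff_spec_mean_crossings
  modality: gyro
  stream: difference
  domain: frequency
  statistic: spec_mean_crossings
- name: gyro_diff_spec_area
  modality: gyro
  stream: difference
  domain: frequency
  statistic: spec_area
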