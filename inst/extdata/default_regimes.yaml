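# Default per-behaviour bout and signal regimes for the synthetic IMU
# generator. Amplitudes: g (accelerometer), deg/s (gyroscope);
# osc_freq_hz is the dominant movement rhythm (0 = aperiodic);
# burst_prob is the per-second rate of high-amplitude transients.
# Prevalences are fractions of recording time and sum to 1, with
# locomotor play fixed at the low-prevalence regime (0.27%) the
# adjusted-count quantifier targets. These are design choices for a
# synthetic benchmark, not measurements of real calves.
regimes:
  - behaviour: "non-active lying"
    prevalence: 0.42
    mean_bout_s: 180
    sd_bout_s: 120
    accel_amp_g: 0.0
    gyro_amp_dps: 0.0
    osc_freq_hz: 0.0
    burst_prob: 0.0
    accel_noise_g: 0.01
    gyro_noise_dps: 0.5
  - behaviour: "active lying"
    prevalence: 0.18
    mean_bout_s: 60
    sd_bout_s: 40
    accel_amp_g: 0.18
    gyro_amp_dps: 45.0
    osc_freq_hz: 2.5
    burst_prob: 0.15
    accel_noise_g: 0.09
    gyro_noise_dps: 12.0
  - behaviour: "ruminating"
    prevalence: 0.20
    mean_bout_s: 120
    sd_bout_s: 80
    accel_amp_g: 0.06
    gyro_amp_dps: 12.0
    osc_freq_hz: 1.2
    burst_prob: 0.0
    accel_noise_g: 0.03
    gyro_noise_dps: 3.0
  - behaviour: "self-grooming"
    prevalence: 0.05
    mean_bout_s: 30
    sd_bout_s: 20
    accel_amp_g: 0.12
    gyro_amp_dps: 25.0
    osc_freq_hz: 3.0
    burst_prob: 0.0
    accel_noise_g: 0.06
    gyro_noise_dps: 6.0
  - behaviour: "nutritive suckling"
    prevalence: 0.05
    mean_bout_s: 90
    sd_bout_s: 40
    accel_amp_g: 0.2
    gyro_amp_dps: 40.0
    osc_freq_hz: 7.9
    burst_prob: 0.0
    accel_noise_g: 0.05
    gyro_noise_dps: 5.0
  - behaviour: "non-nutritive suckling"
    prevalence: 0.0973
    mean_bout_s: 45
    sd_bout_s: 25
    accel_amp_g: 0.15
    gyro_amp_dps: 30.0
    osc_freq_hz: 5.5
    burst_prob: 0.0
    accel_noise_g: 0.05
    gyro_noise_dps: 5.0
  - behaviour: "locomotor play"
    prevalence: 0.0027
    mean_bout_s: 6
    sd_bout_s: 3
    accel_amp_g: 0.3
    gyro_amp_dps: 75.0
    osc_freq_hz: 2.5
    burst_prob: 1.0
    accel_noise_g: 0.15
    gyro_noise_dps: 20.0
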