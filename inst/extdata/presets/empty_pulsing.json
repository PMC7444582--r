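{
  "name": "empty_pulsing",
  "baseline": 1.0,
  "noise_sd": 0.02,
  "onset_delay": 0,
  "pulse_period": 40,
  "pulse_amplitude": 0.4,
  "ramp_rate": 0.0,
  "wave_speed": 0.1,
  "pulse_tau": 8,
  "valve_regime": "pulsing_with_bag",
  "entry_frame": null,
  "neck_close_frame": null,
  "valve_open_frame": null,
  "valve_close_frame": null,
  "exit_outcome": null
}
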