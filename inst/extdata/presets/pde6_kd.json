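{
  "name": "pde6_kd",
  "baseline": 1.0,
  "noise_sd": 0.02,
  "onset_delay": 30,
  "pulse_period": 50,
  "pulse_amplitude": 0.35,
  "ramp_rate": 0.002,
  "wave_speed": 0.1,
  "pulse_tau": 8,
  "valve_regime": "suppressed",
  "entry_frame": 30,
  "neck_close_frame": 110,
  "valve_open_frame": null,
  "valve_close_frame": null,
  "exit_outcome": "trapped"
}
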