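{
  "name": "gsa1_gf",
  "baseline": 1.0,
  "noise_sd": 0.02,
  "onset_delay": 10,
  "pulse_period": 35,
  "pulse_amplitude": 0.15,
  "ramp_rate": 0.003,
  "wave_speed": 0.15,
  "pulse_tau": 6,
  "valve_regime": "entry_spike_then_quiet",
  "entry_frame": 30,
  "neck_close_frame": 100,
  "valve_open_frame": 500,
  "valve_close_frame": 560,
  "exit_outcome": "exited_successfully"
}
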