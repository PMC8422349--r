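{
  "c_m": 1,
  "area": 0.000143,
  "g_na": 100,
  "g_k": 15,
  "e_na": 50,
  "e_k": -80,
  "e_leak": -66,
  "v_shift": -45,
  "g_max_ref": 20,
  "g_leak": 0.047,
  "g_t": 1,
  "provenance": "SYNTHETIC single-compartment reconstruction of the published TRN-neuron simulation (original ModelDB configuration not printed). g_leak and g_t calibrated once to the wild-type anchors (rheobase 0.29 nA, rebound f0 ~255 Hz) by scripts/calibrate_base_model.R, then frozen; variant runs swap only the channel gating parameters."
}
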