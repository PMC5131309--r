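{
  "geometry": {
    "preset": "crevice_channel",
    "channel_h": 0.001,
    "crevice_w": 0.001,
    "crevice_d": 0.0002,
    "length": 0.005,
    "n_across": 20
  },
  "u_in": 0.1,
  "inlet": {
    "RP": 300000000000000,
    "AP": 3000000000000,
    "ADP": 0,
    "TxA2": 0,
    "PT": 1.1e-06,
    "T": 0,
    "AT": 2.844e-06
  },
  "heparin": 0.1,
  "duration": 60,
  "chi": 30,
  "kinetics": [],
  "transport": [],
  "flow": [],
  "output_interval": 1,
  "flow_update_interval": 5,
  "flow_dphi_trigger": 0.08,
  "dt_safety": 0.8,
  "outdir": null,
  "label": "baseline"
}
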