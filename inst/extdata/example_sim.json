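{
  "D_free": 0.05,
  "D_bound": 0,
  "n_particles": 500,
  "n_sites": 40,
  "site_capacity": 40,
  "capture_radius": 0.15,
  "k_on": 4,
  "k_off": 1,
  "dt": 0.1,
  "n_steps": 60,
  "seed": 1,
  "geometry": {"length": 3, "radius": 0.4, "center_xy": [0, 0], "orientation": 0}
}
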