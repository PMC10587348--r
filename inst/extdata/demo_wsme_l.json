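{
  "variant": "wsme_l",
  "fixture": { "n": 12, "topology": "hairpin", "seed": 3 },
  "temperature": 300,
  "eps": 1.0,
  "entropy": { "S_residue": -3.5, "h_scale": 1.0 },
  "linker_threshold": -0.6,
  "seed": 3
}
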