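{
  "_comment": "Example configuration for disulfide-intact folding of hen egg-white lysozyme. The structure and the residue-pair energy table (force-field-derived pairwise energies, kcal/mol) are user-supplied inputs. The constants below are the documented lysozyme values: the four disulfide bonds, the alpha/beta domain regions, and the temperature-dependent contact-energy scale for thermodynamic scans.",
  "variant": "wsme_l_ss_intact",
  "structure": "PATH/TO/lysozyme.pdb",
  "energy_table": "PATH/TO/lysozyme_energies.tsv",
  "temperature": 293,
  "eps": 1.783,
  "entropy": {
    "S_residue": -3.5,
    "h_scale": 1
  },
  "linker_threshold": -0.6,
  "ss_pairs": [
    [6, 127],
    [30, 115],
    [76, 94],
    [64, 80]
  ],
  "region1": [1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13, 14, 15, 16, 17, 18, 19, 20, 21, 22, 23, 24, 25, 26, 27, 28, 29, 30, 31, 32, 33, 34, 35, 36, 37, 38, 39, 86, 87, 88, 89, 90, 91, 92, 93, 94, 95, 96, 97, 98, 99, 100, 101, 102, 103, 104, 105, 106, 107, 108, 109, 110, 111, 112, 113, 114, 115, 116, 117, 118, 119, 120, 121, 122, 123, 124, 125, 126, 127, 128, 129],
  "region2": [40, 41, 42, 43, 44, 45, 46, 47, 48, 49, 50, 51, 52, 53, 54, 55, 56, 57, 58, 59, 60, 61, 62, 63, 64, 65, 66, 67, 68, 69, 70, 71, 72, 73, 74, 75, 76, 77, 78, 79, 80, 81, 82, 83, 84, 85],
  "thermo": {
    "eps_f": 1.783,
    "p": -0.307,
    "q": 11.3,
    "T_f": 293,
    "baseline": 8,
    "T_min": 280,
    "T_max": 360,
    "T_step": 1
  },
  "seed": 1
}
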