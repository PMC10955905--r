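[
  {
    "name": "thoracic-straight-30",
    "length": 100,
    "proximal_diameter": 30,
    "distal_diameter": 30,
    "ring_axial_positions": [10, 30, 50, 70, 90],
    "strut_amplitude": 6,
    "strut_wire_width": 0.5,
    "n_peaks_per_ring": 6,
    "note": "Illustrative straight thoracic tube graft; dimensions representative, not vendor-certified."
  },
  {
    "name": "thoracic-tapered-34-30",
    "length": 100,
    "proximal_diameter": 34,
    "distal_diameter": 30,
    "ring_axial_positions": [10, 30, 50, 70, 90],
    "strut_amplitude": 6,
    "strut_wire_width": 0.5,
    "n_peaks_per_ring": 6,
    "note": "Illustrative tapered thoracic tube graft; dimensions representative, not vendor-certified."
  }
]
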