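[
  {"label": "superficial", "x0": 14, "y0": 8,  "width": 16, "height": 10},
  {"label": "middle",      "x0": 14, "y0": 26, "width": 16, "height": 12},
  {"label": "deep",        "x0": 14, "y0": 44, "width": 16, "height": 12}
]
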