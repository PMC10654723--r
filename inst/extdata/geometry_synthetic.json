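[
  {
    "name": "epidermis",
    "kind": "plane",
    "axis": "z",
    "value": 0
  },
  {
    "name": "intestine",
    "kind": "cylinder",
    "axis": "y",
    "center": [150, 60],
    "radius": 25,
    "range": [0, 300]
  },
  {
    "name": "ventral_nerve_cord",
    "kind": "segment",
    "p1": [100, 0, 20],
    "p2": [100, 300, 20],
    "comment": "synthetic stand-in anatomy for examples and tests"
  },
  {
    "name": "pharynx",
    "kind": "cavity",
    "xmin": 110,
    "xmax": 190,
    "ymin": 100,
    "ymax": 200,
    "entry": [150, 200]
  }
]
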