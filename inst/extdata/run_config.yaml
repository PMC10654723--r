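# Example end-to-end run: simulate a mixed intermingled field, classify,
# and run nearest-neighbor composition plus the permutation null.
seed: 1
n: 1000
extents: [300.0, 300.0, 300.0]
min_sep: 10.0
radius: 5.0
regime: iid
analyses:
  - classify
  - nn
  - "null"
query_class: "neoblast:epidermis"
shuffles: 1000
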