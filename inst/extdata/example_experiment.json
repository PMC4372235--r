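{
  "conditions": {
    "untreated": "untreated",
    "rifampicin": "rifampicin"
  },
  "n_cells": 4,
  "analyses": ["linescan", "kymo", "bleach"],
  "seed": 1
}
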