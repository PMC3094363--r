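{
  "nodes": ["stem wood", "stem bark", "branches total", "foliage total",
            "roots coarse", "aboveground total", "bole",
            "aboveground 1", "aboveground f", "total tree"],
  "steps": [
    {"op": "add", "inputs": ["stem wood", "stem bark"], "output": "bole"},
    {"op": "add", "inputs": ["bole", "branches total", "foliage total"],
     "output": "aboveground 1"},
    {"op": "or", "inputs": ["aboveground 1", "aboveground total"],
     "output": "aboveground f"},
    {"op": "add", "inputs": ["aboveground f", "roots coarse"],
     "output": "total tree"}
  ]
}
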