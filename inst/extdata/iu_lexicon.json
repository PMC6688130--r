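{
  "subjects": ["pojke", "flicka", "mamma"],
  "objects": ["kaka", "burk", "pall", "fonster", "disk", "vatten", "tallrik", "gardin", "golv", "vask", "hylla"],
  "places": ["kok", "tradgard"],
  "actions": ["ramlar", "torkar", "svammar", "racker", "tar", "star", "diskar"]
}
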