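# bluefield pipeline defaults
tile_side: 256
scale_min: 0.50
scale_max: 0.85
color_targets: [170, 100, 160]   # CIELAB8 plant means (L, a, b)
color_correct: true
chroma_threshold: 30             # backdrop when B - max(R,G) >= threshold
min_component_area: 0            # speckle cleanup; 0 = off
translator:
  name: identity                 # identity | stats_transfer | external
placement: random                # random | rows
rows: 2
jitter: 0
n_plants: 4
single_class: true
split: [0.8, 0.1, 0.1]
seed: 0
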