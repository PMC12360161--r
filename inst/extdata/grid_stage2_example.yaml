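# Example refinement (stage-2) grid: overlays applied to the top stage-1
# configurations.
- dropout: 0.0
- dropout: 0.2
- batch_size: 16
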