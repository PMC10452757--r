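metric: HIC
bounds:
- 250.0
- 750.0
- 1250.0
- 1750.0
labels:
- 0-1
- '2'
- '3'
- '4'
- 5-6
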