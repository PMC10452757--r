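metric: CTI
bounds:
- 0.8
- 1.15
- 1.39
- 2.16
labels:
- 0-1
- '2'
- '3'
- '4'
- 5-6
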