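mass: 75.0
k_belt: 110000.0
c_belt: 1500.0
belt_slack: 0.02
k_airbag: 40000.0
c_airbag: 1500.0
airbag_gap: 0.04
k_contact: 900000.0
c_contact: 4000.0
contact_dist: 0.22
w_head:
  belt: 1.0
  airbag: 1.8
  contact: 2.2
w_chest:
  belt: 1.0
  airbag: 1.0
  contact: 1.3
chest_stiffness: 500.0
tail: 0.1
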