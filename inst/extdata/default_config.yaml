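seed: 1
design:
  speeds:
  - 30.0
  - 40.0
  - 50.0
  - 56.0
  - 70.0
  - 80.0
  deploy_times:
  - 2.0
  - 5.0
  - 10.0
  - 20.0
  - 30.0
  - 40.0
  - 50.0
  belt_states:
  - yes
  - no
pulse:
  duration: 0.1
surrogate:
  mass: 75.0
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
criteria:
  max_window: 0.036
  a_int: 85.0
  d_int: 102.0
network:
  n_hidden: 8
  learning_rate: 0.3
  max_epochs: 10000
  target_error: 0.01
  seed: 1
validation:
  n_cases: 200
  noise: 0.25
  seed: 2
  belt_rate: 0.75
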