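name: p04_like
seed: 1
clones:
- clone_id: C0
  parent_id: ~
  n_private_mutations: 150
  ccf:
    peritoneal: 1.0
    liver1: 1.0
    liver2: 1.0
- clone_id: C1
  parent_id: C0
  n_private_mutations: 150
  ccf:
    peritoneal: 1.0
    liver1: 0.0
    liver2: 0.0
- clone_id: C3
  parent_id: C1
  n_private_mutations: 150
  ccf:
    peritoneal: 0.4
    liver1: 0.0
    liver2: 0.0
- clone_id: C2
  parent_id: C0
  n_private_mutations: 150
  ccf:
    peritoneal: 0.0
    liver1: 1.0
    liver2: 1.0
- clone_id: C4
  parent_id: C2
  n_private_mutations: 150
  ccf:
    peritoneal: 0.0
    liver1: 0.0
    liver2: 1.0
samples:
- sample_id: peritoneal
  purity: 0.7
  mean_depth: 150.0
- sample_id: liver1
  purity: 0.7
  mean_depth: 150.0
- sample_id: liver2
  purity: 0.7
  mean_depth: 150.0
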