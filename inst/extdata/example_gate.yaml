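# Example polygon gate for the synthetic data: vertices in
# asinh-transformed coordinates, covering the region where the
# synthetic strain clouds live. Real experiments define their own
# gate per dataset.
channel_x: FSC-H
channel_y: FL1-H
vertices:
  - [0.0, 0.0]
  - [12.0, 0.0]
  - [12.0, 12.0]
  - [0.0, 12.0]
keep_inside: true
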