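# Demo pipeline: one wild-type and one copper-overloaded knockout section,
# quantified against a shared 4-level matrix-matched calibration.
seed: 7
output_dir: elamap_demo_out
elements: ["23Na", "24Mg", "44Ca", "55Mn", "56Fe", "63Cu", "64Zn"]
sections:
  - name: wildtype_9wk
    preset: wildtype_9wk
    width: 64
    height: 64
  - name: atp7b_ko
    preset: atp7b_ko
    width: 64
    height: 64
standards:
  replicates: 1
render: ["63Cu", "56Fe"]
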