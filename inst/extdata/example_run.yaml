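# Example pipeline configuration: seeded Monte-Carlo SOBP delivery to the
# 25 mm water box behind the 43 mm range shifter.
run: irradiate-water
energy: 100.51
rs_thickness: 43
distal_range: 35.5
sobp_width: 18
spacing: 2
mode: mc
events: 200000
seed: 20
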