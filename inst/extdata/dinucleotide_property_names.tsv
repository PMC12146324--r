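index	name
p1	twist
p2	tilt
p3	roll
p4	shift
p5	slide
p6	rise
p7	nn_enthalpy
p8	nn_entropy
p9	nn_free_energy
p10	melting_temperature
p11	stacking_energy
p12	hydrophilicity
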