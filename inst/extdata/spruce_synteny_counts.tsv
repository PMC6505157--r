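quantity	value
lind_comparisons_total	353
lind_comparisons_nonhomologous	11
glauca_comparisons_total	14112
glauca_comparisons_homologous	13084
glauca_nonhomologous_scaffolds	388
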