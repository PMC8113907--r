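n_organs	n_species
0	75
1	405
2	232
3	95
4	11
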