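population_id,molar_n,molar_p,cell_length_um
anc_1,16,1.0239498709535957,6.330775941671942
anc_1_P,16,1.3166029812580375,6.330775941671942
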