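compound_id,Tm_K,dHm_kJ_mol
IP,348.64,26.69
KP,367.99,25.52
FLU,387.34,27.86
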