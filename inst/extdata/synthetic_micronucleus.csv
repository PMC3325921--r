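group,dose_uM,mn_cells,total_cells
control,0,9,1000
colchicine_low,0.005,24,1000
colchicine_high,0.02,47,1000
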