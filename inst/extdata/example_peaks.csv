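peak_id,mass_min,mass_max
peak_1,59.74,60.94
peak_2,75.63,79.55
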