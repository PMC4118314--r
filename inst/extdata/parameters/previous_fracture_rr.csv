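parameter,value,low,high,provenance
rr_any_prev,1.86,1.75,1.98,placeholder
rr_hip_prev,1.95,1.6,2.37,placeholder
rr_osteo_prev,1.86,1.7,2.03,placeholder
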