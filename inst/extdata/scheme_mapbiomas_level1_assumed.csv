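source_code,target_code
1,1
10,1
14,2
22,2
26,3
27,2
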