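surgical_finding,imaging_intact,imaging_dehiscent
control,9,2
fcd,2,27
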