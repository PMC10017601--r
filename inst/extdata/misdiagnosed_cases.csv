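case,error_type,lateral_score,inferior_score,imaging_diagnosis,surgical_finding
1,false_positive,2,1,dehiscent,intact
2,false_positive,1,1,dehiscent,intact
3,false_negative,3,1,intact,dehiscent
4,false_negative,2,2,intact,dehiscent
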