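exposure,or_observed,ci_low,ci_high,or_select_mode
suicidal ideation/attempt,4.92,3.27,7.40,1.71
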