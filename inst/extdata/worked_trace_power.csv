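nest_id,off_start,off_end
N1,2022-06-20T09:05:00Z,2022-06-20T09:10:00Z
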