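# Robustness criterion drive: 1.7 for 1.2 t.u.
include = default
drive_duration = 1.2
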