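# Baseline forward wave: drive 1.7 to E8 for 2 t.u.
include = default
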