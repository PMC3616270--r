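# Backward wave: same network, drive applied to E1
include = default
drive_segment = 1
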