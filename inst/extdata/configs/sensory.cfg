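# Sensory feedback model: alpha = 25, beta = 20, gamma = 17, drive 2.5 t.u.
include = default
alpha = 25
beta = 20
gamma = 17
drive_duration = 2.5
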