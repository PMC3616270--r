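# Rescue regime: weak excitatory chain, sensory feedback restores the wave
include = default
b = 16
alpha = 25
beta = 40
gamma = 0
drive_duration = 1.2
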