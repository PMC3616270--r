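# Two-sided model: E->E contralateral coupling, sustained asymmetric drive
include = default
contralateral_kind = EE
contralateral_weight = 2
P_ext = 1.7
P_ext_right = 1.72
drive_duration = 35
t_end = 40
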