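# Drive strength/duration sweep cell (sustained intermediate drive)
include = default
drive_duration = 35
t_end = 50
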