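quantity	value
total_population	46157822
foreign_population	5220577
foreign_percent_printed	11.3
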