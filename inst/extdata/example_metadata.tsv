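sample_id	group	Gensini
S01	HC	8
S02	HC	12
S03	SCAD	35
S04	SCAD	42
S05	MI	70
S06	MI	66
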