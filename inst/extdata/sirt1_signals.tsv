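protein_id	kind	name	start	end
v1	NES	NES1	30	38
v1	NES	NES2	310	318
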