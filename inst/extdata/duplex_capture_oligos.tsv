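# Blunt double-stranded capture oligo for duplex-capture off-target discovery.
# N = fully randomized base (the 4-bp degenerate overhang that ligates into
# FokI cut sites); phosphorothioate_after lists 1-based positions followed by
# a phosphorothioate linkage; both strands carry a 5'-phosphate.
name	sequence	phosphorothioate_after	modification_5prime
capture_oligo_top	NNNNGTTTAATTGAGTTGTCATATGTTAATAACGGTAT	1,2,36,37	phosphate
capture_oligo_bottom	NNNNATACCGTTATTAACATATGACAACTCAATTAAAC	1,2,36,37	phosphate
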