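>HBG1_promoter_172_199 28-bp segment upstream of the HBG1 transcription start (positions 172-199)
TTCCCCACACTATCTCAATGCAAATATC
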