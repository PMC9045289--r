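name	iupac	max_indels
sigA_minus35	TTGACA	1
sigA_minus10	TATAAT	1
sig54	TGGCACNNNNNTTGCW	1
sigE_minus10	CATACANT	1
sigG_minus10	CATANTA	1
spo0A_box	TGNCGAA	1
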