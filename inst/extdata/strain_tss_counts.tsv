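strain	genome_accession	tss_high_confidence
C_beijerinckii_DSM_6423	GCA_900010805.1	4090
C_beijerinckii_NCIMB_8052	GCA_000016965.1	4583
C_acetobutylicum_ATCC_824	GCA_000008765.1	3441
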