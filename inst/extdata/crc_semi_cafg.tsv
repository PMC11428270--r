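# name: CRC_semi_CAFG
gene_symbol	reference_SE
TIMP3	
RARRES2	
TIMP2	
NOTCH4	3.0
IGFBP6	
ST6GALNAC5	
TGFB1	2.3
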