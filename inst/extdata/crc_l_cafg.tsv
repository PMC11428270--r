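# name: CRC_L_CAFG
gene_symbol	reference_SE
ATF4	
ITGAV	
TGFBR2	
NOTCH2	
TIMP1	
CRELD2	
HIF1A	
MAPK14	
SMAD2	1.5
ROCK1	
ADAM10	
NOTCH1	
MAPK1	
IGF1	6.7
MRC2	
NFKB2	
AKT1	
AKT3	
IGF1R	
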