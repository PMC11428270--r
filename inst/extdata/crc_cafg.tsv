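# name: CRC_CAFG
gene_symbol	reference_SE
SPARC	17.2
FAP	20.2
ACTA2	20.2
VIM	17.8
COL12A1	18.3
DKK3	13.9
INHBA	20.9
ANTXR1	24.3
PDGFRB	14.8
SLC24A3	23.6
ITGA11	16.4
MMP2	18.4
CCL2	18.0
POSTN	15.4
PDPN	11.2
LRRC15	10.5
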