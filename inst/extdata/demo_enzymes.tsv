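# Demonstration restriction-enzyme library: name<TAB>IUPAC recognition motif.
# Twelve well-known enzymes spanning 4-8 bp cutters, degenerate and
# N-containing motifs. Cut positions are not recorded (not used by the tool).
AluI	AGCT
HpaII	CCGG
HindIII	AAGCTT
NotI	GCGGCCGC
XmaI	CCCGGG
BsoBI	CYCGRG
AflII	CTTAAG
AflIII	ACRYGT
BanII	GRGCYC
BaeGI	GKGCMC
ApaI	GGGCCC
NlaIV	GGNNCC
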