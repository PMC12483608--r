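# Ovarian cancer stem-cell marker module (12 genes), one symbol per line.
# Note: the antigen name SSEA1 is not an HGNC symbol; its gene is FUT4,
# listed here under the gene symbol.
PROM1
CD44
ALDH1A1
CD24
KIT
ENG
VCAM1
EPCAM
NES
SOX2
FUT4
THY1
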