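ITGA1
ITGA2
ITGA3
ITGA4
ITGA5
ITGA6
ITGA7
ITGA8
ITGA9
ITGA10
ITGA11
ITGA2B
ITGAD
ITGAE
ITGAL
ITGAM
ITGAV
ITGAX
ITGB1
ITGB2
ITGB3
ITGB4
ITGB5
ITGB6
ITGB7
ITGB8
ICAM1
MUC1
CDH1
CDH2
CD44
DSG2
NCAM1
VCAM1
CD28
CD86
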