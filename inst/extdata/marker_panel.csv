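# Default AFLP/RFLP genotyping panel for AF16 x HK104 C. briggsae hybrid
# lines: nine AFLP indel markers on four autosomes (none on chromosome I)
# plus the X, one mitochondrial RFLP (cb18178) and one X RFLP (cb51757, at
# 12.0 Mbp).  Anchored placements: cb-m205 on III, cb-m124 and cb-m127 on X,
# cb51757 at X:12,000,000.  All other positions (and cb-m103's X assignment,
# standing in for the unnamed third X marker) are editable placeholders.
name,chromosome,position,assay
cb-m26,II,8300000,AFLP
cb-m56,III,3500000,AFLP
cb-m205,III,7300000,AFLP
cb-m161,IV,8700000,AFLP
cb-m172,V,5200000,AFLP
cb-m197,V,14600000,AFLP
cb-m103,X,5300000,AFLP
cb-m124,X,9800000,AFLP
cb-m127,X,16800000,AFLP
cb18178,MT,7000,RFLP
cb51757,X,12000000,RFLP
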