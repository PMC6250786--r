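# Default genome model: approximate C. briggsae chromosome sizes (bp).
# Only relative marker placement matters for the statistics; lengths are
# editable.  Exactly five autosomes, one X and one mitochondrial genome.
chromosome,length,kind
I,15500000,autosome
II,16600000,autosome
III,14600000,autosome
IV,17500000,autosome
V,19500000,autosome
X,21500000,sex_chromosome
MT,14400,mitochondrial
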