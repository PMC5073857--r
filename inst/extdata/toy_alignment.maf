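##maf version=1 scoring=none
a score=0.0
s hg19.chr6 1000 7 + 171115067 ACGTAC-G
s panTro4.chr6 5000 8 + 160000000 ACGTACCG
s mm10.chr10 800 7 + 130000000 A-GTACCG

a score=0.0
s hg19.chr6 1007 4 + 171115067 ACGT
s panTro4.chr6 5008 4 + 160000000 ACNT
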