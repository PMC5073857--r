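((hg19:90,panTro4:90):10,mm10:100);
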