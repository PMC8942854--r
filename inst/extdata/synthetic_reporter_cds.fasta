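>SYNREP synthetic single-tryptophan reporter CDS (W at residue 17)
ATGTCTACTAAAGCTTATGATCTGTTTCGTGGTGAATATGTTCTGAATTGGGCTGAACAA
TCTACTCGTCCTTTTATGGGTCATAAAGAATATTTTGCTCTGGATAAACGTTAA
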