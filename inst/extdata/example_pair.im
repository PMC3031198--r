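example taxon-pair: two nuclear loci and one mtDNA locus
popEast popWest
3
nuc1 3 3 40 1 I
e1        ACGTACGTACGTACGTACGTACGTACGTACGTACGTACGT
e2        ACGTACGTACGTACGTACGAACGTACGTACGTACGTACGT
e3        ACGTACGTACGTACGTACGTACGTACGTACTTACGTACGT
w1        ACGTACGGACGTACGTACGTACGTACGTACGTACGTACGA
w2        ACGTACGGACGTACGTACGTACGTACGTACGTACGTACGA
w3        ACGTACGGACGTACGTACGAACGTACGTACGTACGTACGA
nuc2 2 2 30 1 F
e1        TTGCATTGCATTGCATTGCATTGCATTGCA
e2        TTGCATTGCATTGCATTGCATTGCATTGCA
w1        TTGCATTGCATTGGATTGCATTGCATTGCA
w2        TTGCATTGCATTGGATTGCATTGCATTGAA
mt1 1 1 30 0.25 H
e1        GGATCGGATCGGATCGGATCGGATCGGATC
w1        GGATCGGATCGGATTGGATCGGATCGGATC
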