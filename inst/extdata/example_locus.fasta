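>east_1 pop=1
ACGTACGTACGTACGTACGT
>east_2 pop=1
ACGTACGAACGTACGTACGT
>west_1 pop=2
ACGTACGTACTTACGTACGT
>west_2 pop=2
ACGTACGTACTTACGTACGA
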