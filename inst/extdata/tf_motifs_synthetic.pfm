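>SOX9
A [ 82 85 4 88 80 3 6 5 ]
C [ 6 5 86 4 5 4 2 3 ]
G [ 7 6 5 4 8 5 85 84 ]
T [ 5 4 5 4 7 88 7 8 ]
>GLI1
A [ 4 4 82 3 82 4 4 5 ]
C [ 84 4 5 86 5 4 86 4 ]
G [ 4 4 6 4 6 3 3 84 ]
T [ 5 85 4 4 4 86 4 4 ]
>ZEB1
A [ 3 85 4 4 3 4 4 82 ]
C [ 86 4 86 86 4 84 5 5 ]
G [ 4 4 3 3 4 5 84 5 ]
T [ 4 4 4 4 86 4 4 5 ]
>CTCF
A [ 4 4 84 3 4 4 3 82 4 ]
C [ 85 86 5 87 4 86 4 5 86 ]
G [ 4 3 4 3 85 4 86 6 4 ]
T [ 4 4 4 4 4 3 4 4 3 ]
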