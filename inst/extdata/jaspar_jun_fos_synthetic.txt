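>MA0099.2 Jun::Fos
A [  2  1 38  1  1  2 37 ]
C [  3  2  0 19  2 35  1 ]
G [  1 36  1 18  1  2  1 ]
T [ 33  0  0  1 35  0  0 ]
>SYNDEC01 decoy_gata
A [ 30  0  0 30 30  0  2 ]
C [  2  0  0  2  2  2  2 ]
G [  2 38  0  2  2  2 30 ]
T [  5  1 39  5  5 35  5 ]
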