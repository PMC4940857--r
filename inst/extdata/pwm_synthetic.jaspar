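>SYN0001 NR_DR4
A [ 12  2  2 80  2 30 25 25 25 12  2  2 80  2 30  2 ]
C [  2  2  2  2 90  2 25 25 25  2  2  2  2 90  2  2 ]
G [ 80  90 2  2  2 60 25 25 25 80 90  2  2  2 60  2 ]
T [  6  6 94 16  6  8 25 25 25  6  6 94 16  6  8 94 ]
>SYN0002 NR_DR1
A [ 12  2  2 80  2 30 55 12  2  2 80  2 30  2 ]
C [  2  2  2  2 90  2 15  2  2  2  2 90  2  2 ]
G [ 80 90  2  2  2 60 15 80 90  2  2  2 60  2 ]
T [  6  6 94 16  6  8 15  6  6 94 16  6  8 94 ]
>SYN0003 AP1_TRE
A [  2  6 85  2  2  2 80 ]
C [  2  2  5 90  2 90  6 ]
G [  6 90  5  4  2  4  8 ]
T [ 90  2  5  4 94  4  6 ]
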