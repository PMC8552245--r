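MEME version 4

ALPHABET= ACGT

strands: + -

Background letter frequencies
A 0.25000 C 0.25000 G 0.25000 T 0.25000

MOTIF E2F-a1
letter-probability matrix: alength= 4 w= 8 nsites= 20 E= 0
 0.005000 0.005000 0.005000 0.985000
 0.005000 0.005000 0.005000 0.985000
 0.005000 0.005000 0.005000 0.985000
 0.005000 0.985000 0.005000 0.005000
 0.005000 0.985000 0.005000 0.005000
 0.005000 0.985000 0.005000 0.005000
 0.005000 0.005000 0.985000 0.005000
 0.005000 0.985000 0.005000 0.005000

MOTIF E2F-a2
letter-probability matrix: alength= 4 w= 8 nsites= 20 E= 0
 0.005000 0.005000 0.005000 0.985000
 0.005000 0.005000 0.005000 0.985000
 0.005000 0.005000 0.005000 0.985000
 0.005000 0.005000 0.985000 0.005000
 0.005000 0.005000 0.985000 0.005000
 0.005000 0.985000 0.005000 0.005000
 0.005000 0.005000 0.985000 0.005000
 0.005000 0.985000 0.005000 0.005000

MOTIF E2F-b
letter-probability matrix: alength= 4 w= 8 nsites= 20 E= 0
 0.005000 0.005000 0.005000 0.985000
 0.005000 0.005000 0.005000 0.985000
 0.005000 0.005000 0.005000 0.985000
 0.005000 0.985000 0.005000 0.005000
 0.005000 0.005000 0.985000 0.005000
 0.005000 0.985000 0.005000 0.005000
 0.005000 0.005000 0.985000 0.005000
 0.005000 0.985000 0.005000 0.005000

MOTIF CDE-CHR-a
letter-probability matrix: alength= 4 w= 13 nsites= 20 E= 0
 0.020000 0.020000 0.940000 0.020000
 0.020000 0.020000 0.940000 0.020000
 0.020000 0.940000 0.020000 0.020000
 0.020000 0.020000 0.940000 0.020000
 0.020000 0.020000 0.940000 0.020000
 0.020000 0.020000 0.940000 0.020000
 0.940000 0.020000 0.020000 0.020000
 0.020000 0.020000 0.020000 0.940000
 0.020000 0.020000 0.020000 0.940000
 0.020000 0.020000 0.020000 0.940000
 0.020000 0.020000 0.940000 0.020000
 0.940000 0.020000 0.020000 0.020000
 0.940000 0.020000 0.020000 0.020000

MOTIF CDE-CHR-b
letter-probability matrix: alength= 4 w= 13 nsites= 20 E= 0
 0.020000 0.020000 0.940000 0.020000
 0.020000 0.020000 0.940000 0.020000
 0.020000 0.940000 0.020000 0.020000
 0.020000 0.020000 0.940000 0.020000
 0.020000 0.020000 0.940000 0.020000
 0.940000 0.020000 0.020000 0.020000
 0.940000 0.020000 0.020000 0.020000
 0.020000 0.020000 0.020000 0.940000
 0.020000 0.020000 0.020000 0.940000
 0.020000 0.020000 0.020000 0.940000
 0.020000 0.020000 0.940000 0.020000
 0.940000 0.020000 0.020000 0.020000
 0.940000 0.020000 0.020000 0.020000

MOTIF LONG-a
letter-probability matrix: alength= 4 w= 14 nsites= 20 E= 0
 0.020000 0.940000 0.020000 0.020000
 0.940000 0.020000 0.020000 0.020000
 0.020000 0.940000 0.020000 0.020000
 0.020000 0.020000 0.940000 0.020000
 0.020000 0.020000 0.020000 0.940000
 0.020000 0.020000 0.020000 0.940000
 0.940000 0.020000 0.020000 0.020000
 0.940000 0.020000 0.020000 0.020000
 0.020000 0.940000 0.020000 0.020000
 0.020000 0.020000 0.940000 0.020000
 0.020000 0.020000 0.020000 0.940000
 0.020000 0.020000 0.940000 0.020000
 0.940000 0.020000 0.020000 0.020000
 0.020000 0.940000 0.020000 0.020000

MOTIF LONG-b
letter-probability matrix: alength= 4 w= 14 nsites= 20 E= 0
 0.020000 0.940000 0.020000 0.020000
 0.940000 0.020000 0.020000 0.020000
 0.020000 0.940000 0.020000 0.020000
 0.020000 0.020000 0.940000 0.020000
 0.020000 0.020000 0.020000 0.940000
 0.020000 0.020000 0.020000 0.940000
 0.020000 0.020000 0.020000 0.940000
 0.940000 0.020000 0.020000 0.020000
 0.020000 0.940000 0.020000 0.020000
 0.020000 0.020000 0.940000 0.020000
 0.020000 0.020000 0.020000 0.940000
 0.020000 0.020000 0.940000 0.020000
 0.940000 0.020000 0.020000 0.020000
 0.020000 0.940000 0.020000 0.020000

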