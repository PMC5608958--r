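MEME version 4

ALPHABET= ACGT

strands: + -

Background letter frequencies (from uniform background):
A 0.29000 C 0.21000 G 0.21000 T 0.29000

MOTIF AP-1
letter-probability matrix: alength= 4 w= 7 nsites= 20 E= 0
 0.020000  0.020000  0.020000  0.940000
 0.020000  0.020000  0.940000  0.020000
 0.940000  0.020000  0.020000  0.020000
 0.020000  0.940000  0.020000  0.020000
 0.020000  0.020000  0.020000  0.940000
 0.020000  0.940000  0.020000  0.020000
 0.940000  0.020000  0.020000  0.020000

MOTIF Atf3_CRE
letter-probability matrix: alength= 4 w= 8 nsites= 20 E= 0
 0.020000  0.020000  0.020000  0.940000
 0.020000  0.020000  0.940000  0.020000
 0.940000  0.020000  0.020000  0.020000
 0.020000  0.940000  0.020000  0.020000
 0.020000  0.020000  0.940000  0.020000
 0.020000  0.020000  0.020000  0.940000
 0.020000  0.940000  0.020000  0.020000
 0.940000  0.020000  0.020000  0.020000

MOTIF Egr2
letter-probability matrix: alength= 4 w= 9 nsites= 20 E= 0
 0.020000  0.020000  0.940000  0.020000
 0.020000  0.940000  0.020000  0.020000
 0.020000  0.020000  0.940000  0.020000
 0.020000  0.020000  0.020000  0.940000
 0.020000  0.020000  0.940000  0.020000
 0.020000  0.020000  0.940000  0.020000
 0.020000  0.020000  0.940000  0.020000
 0.020000  0.940000  0.020000  0.020000
 0.020000  0.020000  0.940000  0.020000

MOTIF Sox10
letter-probability matrix: alength= 4 w= 7 nsites= 20 E= 0
 0.020000  0.940000  0.020000  0.020000
 0.020000  0.020000  0.020000  0.940000
 0.020000  0.020000  0.020000  0.940000
 0.020000  0.020000  0.020000  0.940000
 0.020000  0.020000  0.940000  0.020000
 0.020000  0.020000  0.020000  0.940000
 0.020000  0.020000  0.020000  0.940000

MOTIF NFkB
letter-probability matrix: alength= 4 w= 10 nsites= 20 E= 0
 0.020000  0.020000  0.940000  0.020000
 0.020000  0.020000  0.940000  0.020000
 0.020000  0.020000  0.940000  0.020000
 0.940000  0.020000  0.020000  0.020000
 0.020000  0.940000  0.020000  0.020000
 0.020000  0.020000  0.020000  0.940000
 0.020000  0.020000  0.020000  0.940000
 0.020000  0.020000  0.020000  0.940000
 0.020000  0.940000  0.020000  0.020000
 0.020000  0.940000  0.020000  0.020000

MOTIF Mef2
letter-probability matrix: alength= 4 w= 10 nsites= 20 E= 0
 0.020000  0.940000  0.020000  0.020000
 0.020000  0.020000  0.020000  0.940000
 0.940000  0.020000  0.020000  0.020000
 0.940000  0.020000  0.020000  0.020000
 0.940000  0.020000  0.020000  0.020000
 0.940000  0.020000  0.020000  0.020000
 0.940000  0.020000  0.020000  0.020000
 0.020000  0.020000  0.020000  0.940000
 0.940000  0.020000  0.020000  0.020000
 0.020000  0.020000  0.940000  0.020000

MOTIF Gata
letter-probability matrix: alength= 4 w= 8 nsites= 20 E= 0
 0.940000  0.020000  0.020000  0.020000
 0.020000  0.020000  0.940000  0.020000
 0.940000  0.020000  0.020000  0.020000
 0.020000  0.020000  0.020000  0.940000
 0.940000  0.020000  0.020000  0.020000
 0.940000  0.020000  0.020000  0.020000
 0.020000  0.020000  0.940000  0.020000
 0.940000  0.020000  0.020000  0.020000

MOTIF E2f
letter-probability matrix: alength= 4 w= 8 nsites= 20 E= 0
 0.020000  0.020000  0.020000  0.940000
 0.020000  0.020000  0.020000  0.940000
 0.020000  0.020000  0.020000  0.940000
 0.020000  0.940000  0.020000  0.020000
 0.020000  0.940000  0.020000  0.020000
 0.020000  0.940000  0.020000  0.020000
 0.020000  0.020000  0.940000  0.020000
 0.020000  0.940000  0.020000  0.020000

MOTIF Runx
letter-probability matrix: alength= 4 w= 8 nsites= 20 E= 0
 0.020000  0.020000  0.020000  0.940000
 0.020000  0.020000  0.940000  0.020000
 0.020000  0.020000  0.020000  0.940000
 0.020000  0.020000  0.940000  0.020000
 0.020000  0.020000  0.940000  0.020000
 0.020000  0.020000  0.020000  0.940000
 0.020000  0.020000  0.020000  0.940000
 0.020000  0.020000  0.020000  0.940000

MOTIF Oct4
letter-probability matrix: alength= 4 w= 8 nsites= 20 E= 0
 0.940000  0.020000  0.020000  0.020000
 0.020000  0.020000  0.020000  0.940000
 0.020000  0.020000  0.940000  0.020000
 0.020000  0.940000  0.020000  0.020000
 0.940000  0.020000  0.020000  0.020000
 0.940000  0.020000  0.020000  0.020000
 0.940000  0.020000  0.020000  0.020000
 0.020000  0.020000  0.020000  0.940000

MOTIF Klf4
letter-probability matrix: alength= 4 w= 9 nsites= 20 E= 0
 0.020000  0.020000  0.940000  0.020000
 0.020000  0.020000  0.940000  0.020000
 0.020000  0.020000  0.940000  0.020000
 0.020000  0.020000  0.940000  0.020000
 0.020000  0.020000  0.020000  0.940000
 0.020000  0.020000  0.940000  0.020000
 0.020000  0.020000  0.940000  0.020000
 0.020000  0.020000  0.940000  0.020000
 0.020000  0.020000  0.940000  0.020000

MOTIF Tead
letter-probability matrix: alength= 4 w= 8 nsites= 20 E= 0
 0.020000  0.020000  0.940000  0.020000
 0.020000  0.020000  0.940000  0.020000
 0.940000  0.020000  0.020000  0.020000
 0.940000  0.020000  0.020000  0.020000
 0.020000  0.020000  0.020000  0.940000
 0.020000  0.020000  0.940000  0.020000
 0.020000  0.020000  0.020000  0.940000
 0.020000  0.020000  0.940000  0.020000

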