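MEME version 4

ALPHABET= ACGT

strands: + -

Background letter frequencies
A 0.25 C 0.25 G 0.25 T 0.25

MOTIF GATA_like GATA
letter-probability matrix: alength= 4 w= 6 nsites= 20 E= 0
 0.050 0.050 0.850 0.050
 0.850 0.050 0.050 0.050
 0.050 0.050 0.050 0.850
 0.850 0.050 0.050 0.050
 0.050 0.050 0.850 0.050
 0.250 0.250 0.250 0.250

MOTIF TBOX_like TBX
letter-probability matrix: alength= 4 w= 5 nsites= 20 E= 0
 0.880 0.040 0.040 0.040
 0.040 0.040 0.880 0.040
 0.040 0.040 0.880 0.040
 0.040 0.040 0.040 0.880
 0.040 0.040 0.880 0.040
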