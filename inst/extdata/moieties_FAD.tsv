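atom_name	moiety
P	phosphate
O1P	phosphate
O2P	phosphate
O3P	phosphate
PA	phosphate
O1A	phosphate
O2A	phosphate
N9A	adenosine
C8A	adenosine
N7A	adenosine
C5A	adenosine
C6A	adenosine
N6A	adenosine
N1A	adenosine
C2A	adenosine
N3A	adenosine
C4A	adenosine
O5B	adenosine
C5B	adenosine
C4B	adenosine
O4B	adenosine
C3B	adenosine
O3B	adenosine
C2B	adenosine
O2B	adenosine
C1B	adenosine
N1	flavin
C2	flavin
O2	flavin
N3	flavin
C4	flavin
O4	flavin
C4X	flavin
N5	flavin
C5X	flavin
C6	flavin
C7	flavin
C7M	flavin
C8	flavin
C8M	flavin
C9	flavin
C9A	flavin
N10	flavin
C10	flavin
C1'	flavin
C2'	flavin
O2'	flavin
C3'	flavin
O3'	flavin
C4'	flavin
O4'	flavin
C5'	flavin
O5'	flavin
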