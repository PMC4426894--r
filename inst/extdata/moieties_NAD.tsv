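atom_name	moiety
PA	phosphate
O1A	phosphate
O2A	phosphate
O3	phosphate
PN	phosphate
O1N	phosphate
O2N	phosphate
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
N1N	nicotinamide
C2N	nicotinamide
C3N	nicotinamide
C7N	nicotinamide
O7N	nicotinamide
N7N	nicotinamide
C4N	nicotinamide
C5N	nicotinamide
C6N	nicotinamide
O5D	nicotinamide
C5D	nicotinamide
C4D	nicotinamide
O4D	nicotinamide
C3D	nicotinamide
O3D	nicotinamide
C2D	nicotinamide
O2D	nicotinamide
C1D	nicotinamide
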