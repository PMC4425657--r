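# SYNTHETIC squeeze distances (published table unavailable): minimum
# allowed separations (A) between residue i's side sphere and neighbouring
# backbone spheres: CaH(i-1), CO(i-1), NH(i+1), CaH(i+1); co_prev2 is
# CO(i-1) to the side sphere of residue i+1. Default: 80% of full contact.
residue	ca_prev	co_prev	nh_next	ca_next	co_prev2
A	2.96	2.88	2.8	2.96	2.88
C	3.16	3.08	3	3.16	3.08
D	3.24	3.16	3.08	3.24	3.16
E	3.4	3.32	3.24	3.4	3.32
F	3.6	3.52	3.44	3.6	3.52
H	3.48	3.4	3.32	3.48	3.4
I	3.48	3.4	3.32	3.48	3.4
K	3.48	3.4	3.32	3.48	3.4
L	3.48	3.4	3.32	3.48	3.4
M	3.52	3.44	3.36	3.52	3.44
N	3.28	3.2	3.12	3.28	3.2
P	3.24	3.16	3.08	3.24	3.16
Q	3.4	3.32	3.24	3.4	3.32
R	3.6	3.52	3.44	3.6	3.52
S	3.08	3	2.92	3.08	3
T	3.24	3.16	3.08	3.24	3.16
V	3.32	3.24	3.16	3.32	3.24
W	3.76	3.68	3.6	3.76	3.68
Y	3.64	3.56	3.48	3.64	3.56
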