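# SYNTHETIC inner well diameters (A): hard-core contact + 1.2 A
# (published table, derived with the 4.5 A heavy-atom criterion,
# unavailable).
residue	A	C	D	E	F	H	I	K	L	M	N	P	Q	R	S	T	V	W	Y
A	4.9	5.15	5.25	5.45	5.7	5.55	5.55	5.55	5.55	5.6	5.3	5.25	5.45	5.7	5.05	5.25	5.35	5.9	5.75
C	5.15	5.4	5.5	5.7	5.95	5.8	5.8	5.8	5.8	5.85	5.55	5.5	5.7	5.95	5.3	5.5	5.6	6.15	6
D	5.25	5.5	5.6	5.8	6.05	5.9	5.9	5.9	5.9	5.95	5.65	5.6	5.8	6.05	5.4	5.6	5.7	6.25	6.1
E	5.45	5.7	5.8	6	6.25	6.1	6.1	6.1	6.1	6.15	5.85	5.8	6	6.25	5.6	5.8	5.9	6.45	6.3
F	5.7	5.95	6.05	6.25	6.5	6.35	6.35	6.35	6.35	6.4	6.1	6.05	6.25	6.5	5.85	6.05	6.15	6.7	6.55
H	5.55	5.8	5.9	6.1	6.35	6.2	6.2	6.2	6.2	6.25	5.95	5.9	6.1	6.35	5.7	5.9	6	6.55	6.4
I	5.55	5.8	5.9	6.1	6.35	6.2	6.2	6.2	6.2	6.25	5.95	5.9	6.1	6.35	5.7	5.9	6	6.55	6.4
K	5.55	5.8	5.9	6.1	6.35	6.2	6.2	6.2	6.2	6.25	5.95	5.9	6.1	6.35	5.7	5.9	6	6.55	6.4
L	5.55	5.8	5.9	6.1	6.35	6.2	6.2	6.2	6.2	6.25	5.95	5.9	6.1	6.35	5.7	5.9	6	6.55	6.4
M	5.6	5.85	5.95	6.15	6.4	6.25	6.25	6.25	6.25	6.3	6	5.95	6.15	6.4	5.75	5.95	6.05	6.6	6.45
N	5.3	5.55	5.65	5.85	6.1	5.95	5.95	5.95	5.95	6	5.7	5.65	5.85	6.1	5.45	5.65	5.75	6.3	6.15
P	5.25	5.5	5.6	5.8	6.05	5.9	5.9	5.9	5.9	5.95	5.65	5.6	5.8	6.05	5.4	5.6	5.7	6.25	6.1
Q	5.45	5.7	5.8	6	6.25	6.1	6.1	6.1	6.1	6.15	5.85	5.8	6	6.25	5.6	5.8	5.9	6.45	6.3
R	5.7	5.95	6.05	6.25	6.5	6.35	6.35	6.35	6.35	6.4	6.1	6.05	6.25	6.5	5.85	6.05	6.15	6.7	6.55
S	5.05	5.3	5.4	5.6	5.85	5.7	5.7	5.7	5.7	5.75	5.45	5.4	5.6	5.85	5.2	5.4	5.5	6.05	5.9
T	5.25	5.5	5.6	5.8	6.05	5.9	5.9	5.9	5.9	5.95	5.65	5.6	5.8	6.05	5.4	5.6	5.7	6.25	6.1
V	5.35	5.6	5.7	5.9	6.15	6	6	6	6	6.05	5.75	5.7	5.9	6.15	5.5	5.7	5.8	6.35	6.2
W	5.9	6.15	6.25	6.45	6.7	6.55	6.55	6.55	6.55	6.6	6.3	6.25	6.45	6.7	6.05	6.25	6.35	6.9	6.75
Y	5.75	6	6.1	6.3	6.55	6.4	6.4	6.4	6.4	6.45	6.15	6.1	6.3	6.55	5.9	6.1	6.2	6.75	6.6
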