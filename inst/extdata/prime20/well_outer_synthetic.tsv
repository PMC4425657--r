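# SYNTHETIC outer well diameters (A): hard-core contact + 2.4 A
# (published table, derived with the 5.5 A heavy-atom criterion,
# unavailable).
residue	A	C	D	E	F	H	I	K	L	M	N	P	Q	R	S	T	V	W	Y
A	6.1	6.35	6.45	6.65	6.9	6.75	6.75	6.75	6.75	6.8	6.5	6.45	6.65	6.9	6.25	6.45	6.55	7.1	6.95
C	6.35	6.6	6.7	6.9	7.15	7	7	7	7	7.05	6.75	6.7	6.9	7.15	6.5	6.7	6.8	7.35	7.2
D	6.45	6.7	6.8	7	7.25	7.1	7.1	7.1	7.1	7.15	6.85	6.8	7	7.25	6.6	6.8	6.9	7.45	7.3
E	6.65	6.9	7	7.2	7.45	7.3	7.3	7.3	7.3	7.35	7.05	7	7.2	7.45	6.8	7	7.1	7.65	7.5
F	6.9	7.15	7.25	7.45	7.7	7.55	7.55	7.55	7.55	7.6	7.3	7.25	7.45	7.7	7.05	7.25	7.35	7.9	7.75
H	6.75	7	7.1	7.3	7.55	7.4	7.4	7.4	7.4	7.45	7.15	7.1	7.3	7.55	6.9	7.1	7.2	7.75	7.6
I	6.75	7	7.1	7.3	7.55	7.4	7.4	7.4	7.4	7.45	7.15	7.1	7.3	7.55	6.9	7.1	7.2	7.75	7.6
K	6.75	7	7.1	7.3	7.55	7.4	7.4	7.4	7.4	7.45	7.15	7.1	7.3	7.55	6.9	7.1	7.2	7.75	7.6
L	6.75	7	7.1	7.3	7.55	7.4	7.4	7.4	7.4	7.45	7.15	7.1	7.3	7.55	6.9	7.1	7.2	7.75	7.6
M	6.8	7.05	7.15	7.35	7.6	7.45	7.45	7.45	7.45	7.5	7.2	7.15	7.35	7.6	6.95	7.15	7.25	7.8	7.65
N	6.5	6.75	6.85	7.05	7.3	7.15	7.15	7.15	7.15	7.2	6.9	6.85	7.05	7.3	6.65	6.85	6.95	7.5	7.35
P	6.45	6.7	6.8	7	7.25	7.1	7.1	7.1	7.1	7.15	6.85	6.8	7	7.25	6.6	6.8	6.9	7.45	7.3
Q	6.65	6.9	7	7.2	7.45	7.3	7.3	7.3	7.3	7.35	7.05	7	7.2	7.45	6.8	7	7.1	7.65	7.5
R	6.9	7.15	7.25	7.45	7.7	7.55	7.55	7.55	7.55	7.6	7.3	7.25	7.45	7.7	7.05	7.25	7.35	7.9	7.75
S	6.25	6.5	6.6	6.8	7.05	6.9	6.9	6.9	6.9	6.95	6.65	6.6	6.8	7.05	6.4	6.6	6.7	7.25	7.1
T	6.45	6.7	6.8	7	7.25	7.1	7.1	7.1	7.1	7.15	6.85	6.8	7	7.25	6.6	6.8	6.9	7.45	7.3
V	6.55	6.8	6.9	7.1	7.35	7.2	7.2	7.2	7.2	7.25	6.95	6.9	7.1	7.35	6.7	6.9	7	7.55	7.4
W	7.1	7.35	7.45	7.65	7.9	7.75	7.75	7.75	7.75	7.8	7.5	7.45	7.65	7.9	7.25	7.45	7.55	8.1	7.95
Y	6.95	7.2	7.3	7.5	7.75	7.6	7.6	7.6	7.6	7.65	7.35	7.3	7.5	7.75	7.1	7.3	7.4	7.95	7.8
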