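# SYNTHETIC side-chain geometry estimates (published table unavailable).
# side_mass in CH3 units (published; C/W/P filled by the mass/15 rule);
# dr_ca/dr_nh/dr_co: CaH/NH/CO-to-side-sphere (pseudo-)bond lengths (A);
# side_diameter: hard-sphere diameter (A).
residue	side_mass	dr_ca	dr_nh	dr_co	side_diameter
A	1	1.53	2.457	2.492	3.7
C	3.133	2.07	2.921	2.952	4.2
D	3.86	2.47	3.28	3.308	4.4
E	4.793	3.11	3.871	3.896	4.8
F	6.061	3.41	4.153	4.177	5.3
H	5.394	3.15	3.908	3.933	5
I	3.799	2.31	3.135	3.164	5
K	4.865	3.53	4.266	4.29	5
L	3.799	2.6	3.399	3.426	5
M	4.998	2.95	3.722	3.748	5.1
N	3.862	2.46	3.271	3.299	4.5
P	2.8	1.88	2.755	2.787	4.4
Q	4.795	3.09	3.852	3.878	4.8
R	6.728	4.11	4.819	4.841	5.3
S	2.064	1.9	2.772	2.804	4
T	2.997	1.94	2.807	2.839	4.4
V	2.866	1.97	2.833	2.865	4.6
W	8.667	3.87	4.59	4.612	5.7
Y	7.126	3.85	4.571	4.593	5.4
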