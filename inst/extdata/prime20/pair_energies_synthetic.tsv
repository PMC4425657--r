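# SYNTHETIC side-chain pair energies (eps_HB units; published 19-parameter
# table unavailable). Anchors from the published text: eps(F,F) = 0.205,
# salt bridge K-D = 0.136 (original). Positive = attractive well depth,
# negative = repulsive shoulder. Inner/outer wells are 1.3x / 0.7x these.
residue	A	C	D	E	F	H	I	K	L	M	N	P	Q	R	S	T	V	W	Y
A	0.0788	0.0953	0.0254	0.0254	0.1271	0.0572	0.1169	0.0318	0.1169	0.1118	0.0381	0.0699	0.0381	0.0318	0.0445	0.0508	0.1042	0.1271	0.1144
C	0.0953	0.1153	0.0308	0.0308	0.1538	0.0692	0.1414	0.0384	0.1414	0.1353	0.0461	0.0846	0.0461	0.0384	0.0538	0.0615	0.1261	0.1538	0.1384
D	0.0254	0.0308	-0.08	-0.08	0.041	0.0185	0.0377	0.136	0.0377	0.0361	0.0123	0.0226	0.0123	0.136	0.0143	0.0164	0.0336	0.041	0.0369
E	0.0254	0.0308	-0.08	-0.08	0.041	0.0185	0.0377	0.136	0.0377	0.0361	0.0123	0.0226	0.0123	0.136	0.0143	0.0164	0.0336	0.041	0.0369
F	0.1271	0.1538	0.041	0.041	0.205	0.0922	0.1886	0.0512	0.1886	0.1804	0.0615	0.1128	0.0615	0.0512	0.0717	0.082	0.1681	0.205	0.1845
H	0.0572	0.0692	0.0185	0.0185	0.0922	0.0415	0.0849	0.0231	0.0849	0.0812	0.0277	0.0507	0.0277	0.0231	0.0323	0.0369	0.0756	0.0922	0.083
I	0.1169	0.1414	0.0377	0.0377	0.1886	0.0849	0.1735	0.0471	0.1735	0.166	0.0566	0.1037	0.0566	0.0471	0.066	0.0754	0.1547	0.1886	0.1697
K	0.0318	0.0384	0.136	0.136	0.0512	0.0231	0.0471	-0.08	0.0471	0.0451	0.0154	0.0282	0.0154	-0.08	0.0179	0.0205	0.042	0.0512	0.0461
L	0.1169	0.1414	0.0377	0.0377	0.1886	0.0849	0.1735	0.0471	0.1735	0.166	0.0566	0.1037	0.0566	0.0471	0.066	0.0754	0.1547	0.1886	0.1697
M	0.1118	0.1353	0.0361	0.0361	0.1804	0.0812	0.166	0.0451	0.166	0.1588	0.0541	0.0992	0.0541	0.0451	0.0631	0.0722	0.1479	0.1804	0.1624
N	0.0381	0.0461	0.0123	0.0123	0.0615	0.0277	0.0566	0.0154	0.0566	0.0541	0.0184	0.0338	0.0184	0.0154	0.0215	0.0246	0.0504	0.0615	0.0554
P	0.0699	0.0846	0.0226	0.0226	0.1128	0.0507	0.1037	0.0282	0.1037	0.0992	0.0338	0.062	0.0338	0.0282	0.0395	0.0451	0.0925	0.1128	0.1015
Q	0.0381	0.0461	0.0123	0.0123	0.0615	0.0277	0.0566	0.0154	0.0566	0.0541	0.0184	0.0338	0.0184	0.0154	0.0215	0.0246	0.0504	0.0615	0.0554
R	0.0318	0.0384	0.136	0.136	0.0512	0.0231	0.0471	-0.08	0.0471	0.0451	0.0154	0.0282	0.0154	-0.08	0.0179	0.0205	0.042	0.0512	0.0461
S	0.0445	0.0538	0.0143	0.0143	0.0717	0.0323	0.066	0.0179	0.066	0.0631	0.0215	0.0395	0.0215	0.0179	0.0251	0.0287	0.0588	0.0717	0.0646
T	0.0508	0.0615	0.0164	0.0164	0.082	0.0369	0.0754	0.0205	0.0754	0.0722	0.0246	0.0451	0.0246	0.0205	0.0287	0.0328	0.0672	0.082	0.0738
V	0.1042	0.1261	0.0336	0.0336	0.1681	0.0756	0.1547	0.042	0.1547	0.1479	0.0504	0.0925	0.0504	0.042	0.0588	0.0672	0.1378	0.1681	0.1513
W	0.1271	0.1538	0.041	0.041	0.205	0.0922	0.1886	0.0512	0.1886	0.1804	0.0615	0.1128	0.0615	0.0512	0.0717	0.082	0.1681	0.205	0.1845
Y	0.1144	0.1384	0.0369	0.0369	0.1845	0.083	0.1697	0.0461	0.1697	0.1624	0.0554	0.1015	0.0554	0.0461	0.0646	0.0738	0.1513	0.1845	0.166
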