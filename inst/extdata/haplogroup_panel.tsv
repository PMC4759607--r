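haplogroup	position	alt
V	4580	A
J	4216	C
J	10398	G
J	13708	A
J	16069	T
T	4216	C
T	4917	G
T	13368	A
T	16294	T
U	12308	G
K	12308	G
K	12372	A
K	16224	C
W	1243	C
W	8994	A
X	6221	C
X	6371	T
X	14470	C
I	10034	C
I	16129	A
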