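region	patient	morphology	mucin	stroma
1/A	1	Tubular	3	3
1/B	1	Tubular	3	3
2/A	2	Solid	2	2
2/B	2	Normal	–	–
3/A	3	Normal	–	–
3/B	3	Normal	–	–
3/C	3	Tubular	2	1
3/D	3	Papillary	2	1
3/E	3	Papillary	2	3
4/A	4	Papillary	3	2
4/B	4	Papillary	3	3
4/C	4	Papillary	3	2
5/A	5	Solid	–	2
5/B	5	Solid	–	2
5/C	5	Solid	–	3
5/D	5	Solid	–	–
6/A	6	Solid	–	1
6/B	6	Solid	–	1
6/C	6	Solid	–	1
7/A	7	Solid	1	3
7/B	7	Solid	–	3
7/C	7	Normal	–	–
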