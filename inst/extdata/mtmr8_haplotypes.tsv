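## xhaplo haplotype table v1	reference=GRCh37	chrom=X	segment_length_bp=11024
position	63565561	63565562	63565568	63565691	63565818	63566179	63566648	63566740	63566864	63567014	63567951	63568366	63568754	63568859	63569203	63569307	63569355	63569593	63569727	63569969	63569979	63570024	63571405	63571438	63571569	63571733	63571753	63571974	63572010	63572288	63572723	63572886	63573344	63573673	63573863	63575039	63575448
label	1-2	1-2	3	4	5	6	7	8	9	10	11	12	13	14	15	16	17	18	19	20	21	22	23	24	25	26	27	28	29	30	31	32	33	34	35	36	37
ancestral	G	A	C	C	G	G	G	C	A	A	C	A	T	C	T	C	A	A	T	A	A	G	G	A	G	G	G	C	A	A	G	C	C	G	C	A	T
cpg	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	1	0	0	0	0	0	1	0	0	0	0	0	0
@chimpanzee	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.
@neandertal	.	.	.	.	.	A	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.
@denisova	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	N	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.
populations	BantuNE:east	Biaka:west-central	Ethiopian:east	Gabonese:west-central	KhoeSan:south	Mandenka:west-central	Mbuti:west-central	Yoruba:west-central	NonAfrican:non-African
H1	A	G	A	.	.	A	.	.	.	.	.	.	.	.	.	.	.	.	.	.	T	.	.	.	A	.	.	.	.	.	.	.	.	.	.	.	.	|	4	5	3	2	3	6	8	7	0
H2	A	G	A	.	.	A	.	.	.	.	.	.	.	.	.	.	.	.	.	.	T	.	.	.	A	.	.	.	.	.	A	.	.	.	.	.	.	|	0	0	0	0	0	0	1	0	0
H3	A	G	A	.	.	A	.	.	.	.	.	.	.	.	.	.	.	.	.	.	T	.	.	.	A	.	.	.	C	.	.	.	.	.	.	.	.	|	1	0	0	0	0	1	0	0	0
H4	A	G	A	.	.	A	.	.	.	.	.	.	.	.	.	.	.	.	.	.	T	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	|	0	1	0	0	0	0	0	2	0
H5	A	G	A	.	.	A	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	A	.	.	.	.	.	.	.	.	.	.	.	.	|	0	0	0	0	2	0	0	0	0
H6	A	G	A	.	.	A	.	.	.	.	.	.	.	.	.	.	.	.	.	T	T	.	.	.	A	.	.	.	C	.	.	.	.	.	.	.	.	|	0	0	0	0	0	0	0	1	0
H7	A	G	A	.	.	A	.	.	.	.	.	.	.	.	.	.	T	.	.	.	T	.	.	.	A	.	.	.	.	.	.	.	.	.	.	.	.	|	0	0	0	0	1	0	0	0	0
H8	A	G	A	.	.	A	.	.	.	.	.	.	.	.	C	.	.	.	.	.	T	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	|	1	0	0	3	0	0	1	0	0
H9	A	G	A	.	.	A	.	.	.	.	.	.	.	T	.	T	.	.	.	.	.	.	.	.	.	.	.	.	.	.	A	.	.	.	T	.	.	|	1	4	1	5	0	4	0	5	0
H10	A	G	A	.	.	A	.	.	.	.	.	.	A	.	.	.	.	.	.	.	T	.	.	.	A	.	.	.	.	.	.	.	.	.	.	.	.	|	1	0	0	1	0	2	2	0	0
H11	A	G	A	.	.	A	.	.	.	T	.	.	.	.	.	.	.	.	.	.	T	.	.	.	A	.	.	.	.	.	.	.	T	.	.	.	.	|	0	0	0	0	0	0	0	1	0
H12	A	G	A	.	.	A	T	.	.	.	G	G	.	.	.	.	.	.	C	.	.	.	.	.	.	.	.	.	.	.	.	.	.	T	.	G	.	|	1	0	8	0	0	0	0	0	46
H13	A	G	A	.	.	A	T	.	.	.	G	G	.	.	.	.	.	.	C	.	.	.	.	.	.	A	.	.	.	.	.	.	.	T	.	G	.	|	0	0	1	0	0	0	0	0	0
H14	A	G	A	.	.	A	T	.	.	.	G	G	.	.	.	.	.	.	C	.	.	.	A	.	.	.	.	.	.	.	.	.	.	T	.	G	.	|	0	0	0	0	0	0	0	0	1
H15	A	G	A	.	.	A	T	.	.	.	G	G	.	.	.	.	.	.	C	.	.	A	.	.	.	.	.	.	.	.	.	.	.	T	.	G	.	|	0	0	1	0	0	0	0	0	0
H16	A	G	A	T	.	A	T	.	.	.	G	G	.	.	.	.	.	.	C	.	.	A	.	.	.	.	.	.	.	.	.	.	.	T	.	G	.	|	0	0	1	0	1	0	0	0	0
H17	.	.	.	.	.	A	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	T	.	.	.	.	.	.	.	.	.	|	1	0	0	1	7	0	1	0	0
H18	.	.	.	.	.	A	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	C	.	.	.	T	.	.	.	.	.	.	.	.	.	|	0	0	0	0	0	0	0	1	0
H19	.	.	.	.	.	A	.	G	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	G	|	0	0	0	0	2	0	0	0	0
H20	.	.	.	.	.	A	.	G	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	G	.	.	.	.	.	.	G	|	0	0	0	0	1	0	0	0	0
H21	.	.	.	.	.	A	.	G	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	A	.	.	G	.	.	.	.	.	.	G	|	0	0	0	0	1	0	0	0	0
H22	.	.	.	.	T	.	.	.	T	.	.	.	.	.	.	.	.	G	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	|	0	3	0	0	0	0	0	0	0
H23	A	G	A	.	.	A	T	.	.	.	G	G	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	T	.	G	.	|	0	0	0	0	0	0	0	0	1
H24	A	G	A	.	.	A	T	.	.	.	G	G	.	.	.	.	.	.	C	.	.	.	.	.	.	.	.	.	.	.	.	T	.	T	.	G	.	|	0	0	0	0	0	0	0	0	1
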