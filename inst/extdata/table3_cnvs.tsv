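id	cnv_start	cnv_end	length_bp	kind	clones	feature_left	feature_right
1	17101986	17101986	269	gain	AC007981	AT_rich	.
2	17101994	17101994	367	gain	AC023491	AT_rich	.
3	17117298	17117298	216	gain	AC023491	Na	.
4	17213332	17213332	1467	gain	AC007981	AluY/AluSg	.
5	18443137	18443137	849	gain	AC005664	AluY	.
6	21045602	21045602	6065	gain	AC217064	L1PB1	.
7	21082588	21082588	9100	gain	AC009286	L2	.
8	21208336	21208336	11915	gain	AC209546	AluY	.
9	21317338	21317338	322	gain	AC012331	AluSg	.
10	22384885	22384885	8981	gain	AC225552	LTR43	.
11	17091525	17092039	514	loss	AC008079/AC007981/AC023491	L1M4c	L1M4c
12	17147850	17148359	509	loss	AC023491	AluY	AluSx
13	17255132	17256943	1811	loss	AC007981	AluSx	Na
14	17259091	17259821	730	loss	AC007325	(TATAA)n	(TA)n
15	18619242	18619474	232	loss	AC006549	(CACCAT)n	Na
16	18635423	18636050	627	loss	AC006549	Na	Na
17	19188424	19189864	1440	loss	AC004033	Na	AluSc
18	19280623	19283840	3217	loss	AC214993	MLT2B1	AluJb
19	19751004	19776895	25891	loss	AC002049	AluY	AluJb
20	19813055	19814522	1467	loss	AC008018	AluY	AluY
21	19867770	19868094	324	loss	AC008018	Na	Na
22	19964433	19965896	1463	loss	AC007708	AluY	AluY
23	19964603	19966056	1453	loss	AC009288	AluY	AluY
24	19964603	19966061	1458	loss	AC012330	AluY	AluY
25	20352325	20353913	1588	loss	AC018751	AluSx	AluSx
26	22230772	22233234	2462	loss	AP000346	AluJb	Na
27	22604144	22641299	37155	loss	AC158336	Na	Na
28	22673453	22727704	54251	loss	AP000352	Subunit/GSTTP	Subunit/GSTTP
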