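index	cnv_start	cnv_end	length_bp	kind	left_subunit_start	left_subunit_end	right_subunit_start	right_subunit_end	family_id	block	technology
1	17108337	17249642	141305	gain	17106814	17116867	17241175	17251240	80	LCR22-2'	aCGH
2	17108337	17249642	141305	loss	17106814	17116867	17241175	17251240	80	LCR22-2'	aCGH
3	21346546	21412512	65966	loss	21344443	21350044	21410029	21415309	42	LCR22-5'	sequencing
4	21350920	21372688	21768	loss	21350334	21351679	21371980	21373335	52	LCR22-5'	sequencing
5	21359730	21420692	60962	loss	21359721	21367895	21420384	21428665	58	LCR22-5'	sequencing
6	21364900	21425105	60205	loss	21359721	21367895	21420384	21428665	58	LCR22-5'	sequencing
7	21378929	21437071	58142	loss	21376652	21382799	21434410	21440989	94	LCR22-5'	sequencing
8	21381357	21439879	58522	loss	21376652	21382799	21434410	21440989	94	LCR22-5'	sequencing
9	21430381	21494380	63999	loss	21429486	21431884	21493407	21495966	71	LCR22-5'	sequencing
10	22245900	22313362	67462	loss	22244487	22248921	22309895	22314095	98	LCR22-6'	PairedEndMapping
11	22247409	22311770	64361	loss	22244487	22248921	22309895	22314095	98	LCR22-6'	aCGH
12	22291744	22295976	4232	loss	22288656	22292395	22292394	22296670	6	LCR22-6'	sequencing
13	22626028	22660855	34827	loss	22621224	22626431	22659321	22664520	8	LCR22-7'	aCGH
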