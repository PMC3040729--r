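chromA	startA	endA	chromB	startB	endB	strand	fracMatch
chr22	17100001	17102000	chr22	17110001	17112000	+	0.95
chr22	17102001	17104000	chr22	17120001	17122000	+	0.95
chr22	17103001	17105000	chr22	17130001	17132000	+	0.96
chr22	17131001	17133000	chr22	17141001	17143000	+	0.97
chr22	17101001	17102000	chr22	17140001	17141000	+	0.94
chr22	17121001	17122000	chr22	17130001	17131000	+	0.95
chr22	17104001	17105000	chr22	17141001	17142000	+	0.98
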