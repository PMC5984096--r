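rsid	effect_allele	other_allele	eaf	beta	se	pval	n
rs8000013	A	C	0.1	0.010649952854376308	0.016854385448987673	0.5274651466525322	79845
rs8000026	A	G	0.1388888888888889	0.0022241227180490137	0.014620789622951918	0.879091847688385	79845
rs8000039	C	A	0.17777777777777778	0.024540701450424945	0.013225156948730275	0.06350951280763344	79845
rs8000052	C	T	0.21666666666666667	0.0017937931091582407	0.012273398113924793	0.8838006619936547	79845
rs8000065	G	A	0.25555555555555554	0.021958152227661874	0.011592453607269883	0.05820159739451854	79845
rs8000078	G	T	0.29444444444444445	0.013409470590090108	0.011093456539289373	0.22675007251251228	79845
rs8000091	T	C	0.33333333333333337	0.007783745205829218	0.010726065219339954	0.46803186698821714	79845
rs8000104	T	G	0.37222222222222223	0.003862289363064924	0.010459960836225442	0.7119450367937745	79845
rs8000117	A	C	0.4111111111111111	-0.008022777694531885	0.010276326377406119	0.4349761159325817	79845
rs8000130	A	G	0.45	-0.00702133590977498	0.010163576837512338	0.4896703938398785	79845
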