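rsid	effect_allele	other_allele	eaf	beta	se	pval	n
rs8000013	A	C	0.1	0.12179993911361402	0.026478247633394354	4.2249094050057074e-06	32330
rs8000026	A	G	0.1388888888888889	0.10667948691775968	0.022969267518177922	3.4099278876109172e-6	32330
rs8000039	C	A	0.17777777777777778	0.09741976867668917	0.020776727916829447	2.7469248087049073e-6	32330
rs8000052	C	T	0.21666666666666667	0.09126583449694435	0.019281514330340355	2.208623288847198e-6	32330
rs8000065	G	A	0.25555555555555554	0.08701169532075466	0.018211750183413766	1.7724310418226221e-6	32330
rs8000078	G	T	0.29444444444444445	0.08404084765227553	0.017427825550011055	1.4196765493648305e-6	32330
rs8000091	T	C	0.33333333333333337	0.08200651423513292	0.01685065360995882	1.1349621448544346e-6	32330
rs8000104	T	G	0.37222222222222223	0.0807023416152092	0.016432603496309563	9.056175011871436e-7	32330
rs8000117	A	C	0.4111111111111111	0.08000305220338072	0.016144113673327947	7.21239102579255e-7	32330
rs8000130	A	G	0.45	0.07983492046007719	0.015966984092015437	5.733031437583878e-7	32330
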