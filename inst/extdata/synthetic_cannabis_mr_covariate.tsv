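rsid	effect_allele	other_allele	eaf	beta	se	pval	n
rs8000013	A	C	0.1	0.04288691740787046	0.01412784446427271	0.0024003321960975087	111898
rs8000026	A	G	0.1388888888888889	0.04968486882020171	0.012255578369386571	5.0335966867849216e-5	111898
rs8000039	C	A	0.17777777777777778	0.001331368566378558	0.011085717776703577	0.9044058001754778	111898
rs8000052	C	T	0.21666666666666667	0.07345267559236071	0.010287925366750304	9.353649648730895e-13	111898
rs8000065	G	A	0.25555555555555554	0.031491509116658475	0.009717137537793937	0.00119185752295201	111898
rs8000078	G	T	0.29444444444444445	0.024582185795435276	0.009298863434244216	0.008203707726043426	111898
rs8000091	T	C	0.33333333333333337	0.05031718565218039	0.008990905161812456	2.187805458842629e-8	111898
rs8000104	T	G	0.37222222222222223	0.03645543470432301	0.008767848596072832	3.21251166632564e-5	111898
rs8000117	A	C	0.4111111111111111	0.04187494058554549	0.00861392076047583	1.1661137265549292e-6	111898
rs8000130	A	G	0.45	0.05151661737744102	0.008519410760816758	1.4759564765544532e-9	111898
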