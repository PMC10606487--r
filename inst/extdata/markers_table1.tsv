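chromosome	locus	probe	range_bp
11	D11S910	AFM154yh2	249-261
11	D11S912	AFM157xh6	101-123
11	D11S925	AFM220yb6	173-199
11	D11S934	AFM248wf5	230-
11	D11S968	AFM109xc3	137-155
11	D11S1984	GGAA17G05	166-206
11	D11S1392	GATA6B09	200-220
11	D11S1999	GATA23F06	109-137
11	D11S2000	GATA28D01	199-235
11	D11S2371	GATA90D07	193-213
11	D11S4464	GATA64D03	225-249
17	D17S250	Mfd15	151-169
17	D17S787	AFM095tc5	138-166
17	D17S789	AFM107yb8	154-170
17	D17S793	AFM165zd4	95-109
17	D17S798	AFM179xg11	218-
17	D17S799	AFM192yh2	186-200
17	D17S807	AFM234xc9	114-138
17	D17S809	AFM157xh6	229-247
17	D17S928	AFM217yd10	135-165
17	D17S934	-	174-
17	D17S1290	GATA49C09	170-210
17	D17S1293	GGAA7D11	262-290
17	D17S1301	GATA28D11	147-163
17	D17S1303	GATA64B04	225-245
17	D17S1308	GATAT1A05	304-316
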