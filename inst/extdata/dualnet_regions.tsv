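network	region	x	y	z	ON1	ON2	ON3	ON4	ON5	ON6	ON7	dkl_scaled_published
FP	R-IPS	29	-65	42	0.35	0	0.649	0	0	0	0	0.505
FP	L-IPS	-31	-62	45	0.485	0	0.513	0	0	0	0	0.469
FP	R-FC	42	2	37	0	0	0.446	0	0	0	0.553	0.475
FP	L-FC	-42	3	38	0.407	0	0.591	0	0	0	0	0.482
FP	R-Precuneus	10	-73	43	0.536	0	0.208	0.255	0	0	0	0.228
FP	L-Precuneus	-9	-76	40	0.888	0	0	0.111	0	0	0	0.735
FP	mid-Cingulate	-1	-31	31	0.998	0	0	0	0	0	0	1
FP	R-IPL	50	-51	45	0.728	0	0	0	0	0.271	0	0.554
FP	L-IPL	-51	-54	37	0.615	0	0	0	0	0.383	0	0.489
FP	R-dlPFC	44	21	34	0.875	0	0.086	0	0	0	0.038	0.656
FP	L-dlPFC	-44	22	36	0.998	0	0	0	0	0	0	1
CO	R-aIfO	38	19	0	0.261	0	0.171	0	0	0	0.567	0.255
CO	L-aIfO	-36	17	3	0	0	0.073	0	0	0	0.925	0.799
CO	dACC/msFC	-2	7	50	0	0.426	0	0	0.195	0	0.377	0.195
CO	R-APFC	28	51	25	0.641	0	0	0	0	0.274	0.084	0.352
CO	L-APFC	-28	54	6	0.998	0	0	0	0	0	0	1
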