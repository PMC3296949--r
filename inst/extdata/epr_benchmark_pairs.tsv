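dataset	structure	chain_a	resno_a	chain_b	resno_b	epr_mean	epr_pk	cb_ref	pred_mean_ref	pred_pk_ref	thor_a	thor_b	vdw_a	vdw_b
t4l	2LZM	A	61	A	135	47.2	NA	40	49	50	normal	normal	3.4	3.4
t4l	2LZM	A	65	A	135	46.3	NA	37	47	47	normal	normal	3.4	3.4
t4l	2LZM	A	61	A	86	37.5	NA	37	45	46	normal	normal	3.4	3.4
t4l	2LZM	A	65	A	86	37.4	NA	31	37	38	normal	normal	3.4	3.4
t4l	2LZM	A	80	A	135	36.8	NA	27	36	38	normal	normal	3.4	3.4
t4l	2LZM	A	61	A	80	34	NA	29	34	33	normal	normal	3.4	3.4
t4l	2LZM	A	65	A	80	26.5	NA	22	25	24	normal	normal	3.4	3.4
t4l	2LZM	A	119	A	131	25	NA	13	24	25	normal	normal	3.4	3.4
t4l	2LZM	A	123	A	131	23	NA	14	24	25	normal	normal	3.4	3.4
t4l	2LZM	A	65	A	76	21.4	NA	17	18	19	normal	normal	3.4	3.4
t4l	2LZM	A	116	A	131	19	NA	11	18	19	normal	normal	3.4	3.4
t4l	2LZM	A	119	A	128	19	NA	9.7	18	19	normal	normal	3.4	3.4
t4l	2LZM	A	140	A	151	18	NA	17	21	21	normal	normal	3.4	3.4
t4l	2LZM	A	89	A	93	16	NA	12	17	17	normal	normal	3.4	3.4
t4l	2LZM	A	86	A	119	15	NA	10	13	12	normal	normal	3.4	3.4
t4l	2LZM	A	120	A	131	14	NA	9	12	12	thorough	thorough	3.2	3.4
t4l	2LZM	A	127	A	151	14	NA	12	14	14	normal	normal	3.4	3.4
t4l	2LZM	A	59	A	159	41.9	42	34	43	43	normal	normal	3.4	3.4
t4l	2LZM	A	60	A	90	37.8	38	37	45	46	normal	normal	3.4	3.4
t4l	2LZM	A	60	A	94	25.5	26	28	31	32	normal	normal	3.4	3.4
t4l	2LZM	A	60	A	109	35.2	34	31	39	40	normal	normal	3.4	3.4
t4l	2LZM	A	60	A	154	34.1	34	34	38	39	normal	thorough	3.4	3.4
t4l	2LZM	A	62	A	134	41.1	41	36	48	48	thorough	thorough	3.4	3.4
t4l	2LZM	A	64	A	122	34.1	33	33	38	38	normal	normal	3.4	3.4
t4l	2LZM	A	82	A	94	30.7	32	24	32	33	normal	normal	3.4	3.4
t4l	2LZM	A	82	A	132	26.3	29	21	28	27	normal	normal	3.4	3.4
t4l	2LZM	A	82	A	155	35.8	38	28	38	39	normal	normal	3.4	3.4
t4l	2LZM	A	83	A	123	20.5	21	15	17	17	normal	normal	3.4	3.4
t4l	2LZM	A	93	A	112	26.1	26	21	32	33	thorough	thorough	3.4	3.2
t4l	2LZM	A	93	A	123	24.8	25	19	26	27	normal	normal	3.4	3.4
t4l	2LZM	A	93	A	154	25.1	25	16	26	27	normal	thorough	3.4	3.4
t4l	2LZM	A	94	A	132	31.7	32	19	32	33	thorough	thorough	3.4	3.4
t4l	2LZM	A	108	A	155	35.2	36	25	37	37	normal	normal	3.4	3.4
t4l	2LZM	A	109	A	134	30.6	31	21	31	33	normal	normal	3.4	3.4
t4l	2LZM	A	115	A	155	28.2	27	23	33	33	normal	normal	3.4	3.4
t4l	2LZM	A	116	A	134	20.2	20	12	17	17	normal	normal	3.4	3.4
histone	1TZY	A	46	C	46	60	60	51	61	64	normal	normal	3.4	3.4
histone	1TZY	A	49	C	49	63	63	54	65	66	normal	normal	3.4	3.4
histone	1TZY	A	65	C	65	70	70	66	76	76	normal	normal	3.4	3.4
histone	1TZY	A	76	C	76	68	70	61	71	71	normal	normal	3.4	3.4
histone	1TZY	A	90	C	90	57	59	50	61	62	normal	normal	3.4	3.4
histone	1TZY	A	125	C	125	29	28	20	30	31	normal	normal	3.4	3.4
histone	1TZY	B	25	D	25	73	67	59	71	71	normal	normal	3.4	3.4
histone	1TZY	B	30	D	30	66	67	55	66	66	normal	normal	3.4	3.4
histone	1TZY	B	45	D	45	35	33	31	35	34	normal	normal	3.4	3.4
histone	1TZY	B	47	D	47	35	26	30	32	33	normal	normal	3.4	3.4
histone	1TZY	B	49	D	49	45	46	34	41	41	normal	normal	3.4	3.4
histone	1TZY	B	60	D	60	39	38	32	38	38	normal	normal	3.4	3.4
histone	1TZY	B	63	D	63	40	46	39	47	48	normal	normal	3.4	3.4
histone	1TZY	B	67	D	67	45	45	38	44	44	painstaking	painstaking	3.4	3.4
histone	1TZY	B	71	D	71	45	43	36	47	46	thorough	thorough	3.0	3.0
histone	1TZY	B	82	D	82	53	51	44	50	50	thorough	thorough	3.0	3.0
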