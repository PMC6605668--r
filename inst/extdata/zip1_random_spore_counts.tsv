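background	genotype	strain	interval	chromosome	r	t	pct	pct_control	pct_chr	pct_chr_control
pch2	pch2	AM3724	HIS4-CEN3	III	726	2714	26.8	100	113.4	100
pch2	pch2	AM3724	CEN3-MAT	III	713	2714	26.3	100	NA	NA
pch2	pch2	AM3724	MAT-RAD18	III	975	2714	35.9	100	NA	NA
pch2	pch2	AM3724	RAD18-HMR	III	663	2714	24.4	100	NA	NA
pch2	pch2	AM3724	SPO11-SPO13	VIII	988	2714	36.4	100	92.6	100
pch2	pch2	AM3724	SPO13-THR1	VIII	460	2714	16.9	100	NA	NA
pch2	pch2	AM3724	THR1-LYS2	VIII	1066	2714	39.3	100	NA	NA
pch2	pch2 msh4	AM4025	HIS4-CEN3	III	142	1684	8.4	31	38.2	34
pch2	pch2 msh4	AM4025	CEN3-MAT	III	87	1684	5.2	20	NA	NA
pch2	pch2 msh4	AM4025	MAT-RAD18	III	235	1684	14.0	39	NA	NA
pch2	pch2 msh4	AM4025	RAD18-HMR	III	180	1684	10.7	44	NA	NA
pch2	pch2 msh4	AM4025	SPO11-SPO13	VIII	163	1684	9.7	18	40.0	43
pch2	pch2 msh4	AM4025	SPO13-THR1	VIII	119	1684	7.1	42	NA	NA
pch2	pch2 msh4	AM4025	THR1-LYS2	VIII	392	1684	23.3	59	NA	NA
pch2	pch2 zip1	AM4023	HIS4-CEN3	III	124	1208	10.3	38	46.7	41
pch2	pch2 zip1	AM4023	CEN3-MAT	III	134	1208	11.1	42	NA	NA
pch2	pch2 zip1	AM4023	MAT-RAD18	III	180	1208	14.9	42	NA	NA
pch2	pch2 zip1	AM4023	RAD18-HMR	III	126	1208	10.4	43	NA	NA
pch2	pch2 zip1	AM4023	SPO11-SPO13	VIII	267	1208	22.1	61	58.9	64
pch2	pch2 zip1	AM4023	SPO13-THR1	VIII	122	1208	10.1	60	NA	NA
pch2	pch2 zip1	AM4023	THR1-LYS2	VIII	322	1208	26.7	68	NA	NA
pch2	pch2 zip1[d2-163]	AM3725	HIS4-CEN3	III	225	2494	9.0	34	44.3	39
pch2	pch2 zip1[d2-163]	AM3725	CEN3-MAT	III	225	2494	9.0	34	NA	NA
pch2	pch2 zip1[d2-163]	AM3725	MAT-RAD18	III	409	2494	16.4	46	NA	NA
pch2	pch2 zip1[d2-163]	AM3725	RAD18-HMR	III	246	2494	9.9	41	NA	NA
pch2	pch2 zip1[d2-163]	AM3725	SPO11-SPO13	VIII	39	2494	13.6	37	46.0	50
pch2	pch2 zip1[d2-163]	AM3725	SPO13-THR1	VIII	201	2494	8.1	48	NA	NA
pch2	pch2 zip1[d2-163]	AM3725	THR1-LYS2	VIII	606	2494	24.3	62	NA	NA
pch2	pch2 zip1 msh4	AM4026	HIS4-CEN3	III	56	529	10.6	40	46.7	41
pch2	pch2 zip1 msh4	AM4026	CEN3-MAT	III	63	529	11.9	45	NA	NA
pch2	pch2 zip1 msh4	AM4026	MAT-RAD18	III	77	529	14.6	41	NA	NA
pch2	pch2 zip1 msh4	AM4026	RAD18-HMR	III	51	529	9.6	39	NA	NA
pch2	pch2 zip1 msh4	AM4026	SPO11-SPO13	VIII	154	529	29.1	80	56.0	60
pch2	pch2 zip1 msh4	AM4026	SPO13-THR1	VIII	47	529	8.9	53	NA	NA
pch2	pch2 zip1 msh4	AM4026	THR1-LYS2	VIII	95	529	18.0	46	NA	NA
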