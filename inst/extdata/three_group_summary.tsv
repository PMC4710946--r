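variable	group	mean	sd	n	printed_F	printed_df2
age	AD	69.4	11.1	25	1.52	95
age	MCI	67.9	9.5	31	1.52	95
age	NC	65.6	7.1	42	1.52	95
education	AD	8.3	5.4	25	2.4	95
education	MCI	10.1	5.0	31	2.4	95
education	NC	11.1	4.9	42	2.4	95
MMSE	AD	16.8	4.7	25	93.04	95
MMSE	MCI	23.5	2.9	31	93.04	95
MMSE	NC	28.0	2.3	42	93.04	95
MoCA	AD	12.8	4.8	24	81.32	73
MoCA	MCI	18.3	3.9	22	81.32	73
MoCA	NC	26.0	2.8	30	81.32	73
CDT	AD	1.7	1.1	23	23.39	87
CDT	MCI	1.8	0.8	29	23.39	87
CDT	NC	2.9	0.4	38	23.39	87
AVLT_I	AD	3.6	1.5	25	108.87	95
AVLT_I	MCI	4.6	1.3	31	108.87	95
AVLT_I	NC	9.3	2.1	42	108.87	95
AVLT_D	AD	0.6	1.1	25	159.79	95
AVLT_D	MCI	2.7	2.2	31	159.79	95
AVLT_D	NC	10.4	3.0	42	159.79	95
AVLT_R	AD	3.4	3.1	25	72.48	95
AVLT_R	MCI	7.1	3.9	31	72.48	95
AVLT_R	NC	12.4	2.1	42	72.48	95
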