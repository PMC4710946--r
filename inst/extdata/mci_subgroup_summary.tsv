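variable	phase	subgroup	mean	sd	n	printed_t	printed_df
age	baseline	MCI_c	68.6	9.3	21	0.57	29
age	baseline	MCI_nc	66.5	10.4	10	0.57	29
education	baseline	MCI_c	10.5	4.6	21	0.66	29
education	baseline	MCI_nc	9.2	5.9	10	0.66	29
MMSE	baseline	MCI_c	23.5	2.9	21	-0.07	29
MMSE	baseline	MCI_nc	23.6	3.2	10	-0.07	29
AVLT_I	baseline	MCI_c	4.4	1.2	21	-0.96	29
AVLT_I	baseline	MCI_nc	4.9	1.4	10	-0.96	29
AVLT_D	baseline	MCI_c	2.3	1.9	21	-1.60	29
AVLT_D	baseline	MCI_nc	3.6	2.6	10	-1.60	29
AVLT_R	baseline	MCI_c	6.6	4.2	21	-0.99	29
AVLT_R	baseline	MCI_nc	8.1	3.1	10	-0.99	29
MMSE	followup	MCI_c	20.0	4.2	21	-2.59	24
MMSE	followup	MCI_nc	24.4	2.9	10	-2.59	24
MoCA	followup	MCI_c	15.8	4.3	21	-1.69	24
MoCA	followup	MCI_nc	19.0	4.0	10	-1.69	24
CDT	followup	MCI_c	1.7	0.9	21	-1.23	24
CDT	followup	MCI_nc	2.1	0.7	10	-1.23	24
AVLT_I	followup	MCI_c	4.1	1.3	21	-2.44	24
AVLT_I	followup	MCI_nc	5.5	1.3	10	-2.44	24
AVLT_D	followup	MCI_c	1.7	2.3	21	-1.99	24
AVLT_D	followup	MCI_nc	3.4	2.0	10	-1.99	24
AVLT_R	followup	MCI_c	6.1	3.8	21	-1.76	24
AVLT_R	followup	MCI_nc	8.3	2.1	10	-1.76	24
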