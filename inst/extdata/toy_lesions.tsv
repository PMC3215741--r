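sample_id	chrom	start	end	n_markers	mean_lrr	cn_estimate	cn_state	loh	n_informative	category	length
T01	chr1	10001	10901	12	1.02	4.1	gain	FALSE	15	AMP_NO_LOH	900
T02	chr2	1000001	1900001	850	0.01	2.0	neutral	TRUE	260	AUPD	900000
T03	chrX	5000001	5100001	95	0.98	3.9	gain	FALSE	30	AMP_NO_LOH	100000
T04	chr1	1550001	1600001	48	1.05	4.1	gain	FALSE	16	AMP_NO_LOH	50000
T05	chr1	2200001	2260001	60	-0.95	1.0	loss	TRUE	20	DEL_LOH	60000
T06	chr2	3000001	4300001	1250	0.02	2.0	neutral	TRUE	400	AUPD	1300000
T07	chr3	500001	540001	41	0.60	3.0	gain	FALSE	14	AMP_NO_LOH	40000
T08	chr3	7000001	7025001	26	-1.10	0.9	loss	TRUE	9	DEL_LOH	25000
T09	chr4	100001	180001	78	-0.30	1.6	loss	FALSE	25	DEL_NO_LOH	80000
T10	chr4	9000001	9090001	88	1.55	5.9	gain	TRUE	28	AMP_LOH	90000
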