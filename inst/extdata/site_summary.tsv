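site_code	n	d18O_vpdb_min	d18O_vpdb_max	d18O_vpdb_mean	d18O_vpdb_sd	d18O_vsmow_min	d18O_vsmow_max	d18O_vsmow_mean	d18O_vsmow_sd	d13C_min	d13C_max	d13C_mean	d13C_sd
FR	18	-9.0	-4.5	-6.4	1.2	21.6	26.3	24.4	1.2	-13.4	-9.5	-11.6	1.1
SS	50	-6.0	-2.7	-4.0	0.6	24.7	28.1	26.8	0.6	-14.9	-9.9	-13.1	0.9
CE	3	-6.4	-5.9	-6.2	0.3	24.3	24.8	24.5	0.3	-13.6	-11.1	-12.4	1.3
OC	16	-6.9	-3.2	-4.6	0.2	23.8	27.6	26.2	0.9	-14.2	-12.5	-13.7	0.1
CM	7	-5.6	-3.9	-4.7	0.5	25.1	26.9	26.0	0.5	-13.4	-11.5	-12.7	0.7
TC	4	-4.7	-3.9	-4.4	0.4	26.1	26.9	26.4	0.4	-14.2	-12.7	-13.6	0.6
PB	3	-4.6	-4.5	-4.6	0.1	26.2	26.3	26.2	0.1	-13.4	-11.5	-12.3	1.0
GN	7	-4.8	-3.1	-3.9	0.5	26.0	27.7	26.9	0.5	-13.1	-11.8	-12.5	0.5
PA	9	-6.2	-4.2	-5.4	0.6	24.5	26.6	25.4	0.7	-12.7	-11.4	-12.2	0.5
MC	9	-5.6	-4.4	-4.9	0.5	25.1	26.4	25.9	0.5	-11.3	-3.8	-7.9	2.9
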