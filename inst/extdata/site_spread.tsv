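group	iqr	mad_raw	mad_norm	mad_q3
FR	0.9	0.5	0.7	NA
SS	0.7	0.3	NA	0.5
rome_copper_age	0.4	0.2	NA	0.3
PA	0.9	0.3	NA	0.4
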