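sample	source	lymphocytes	macrophages	neutrophils	mast_cells	eosinophils
horse1	balf_cytology	55.8	25.8	5.8	12.8	0
horse1	suspension_cytology	60.8	22.8	4.0	12.3	0
horse1	scrnaseq	85.3	7.4	3.4	3.8	0
horse2	balf_cytology	40.5	44.0	14.5	1.0	0
horse2	suspension_cytology	39.5	48.0	12.0	0.5	0
horse2	scrnaseq	74.7	13.7	10.5	1.1	0
horse3	balf_cytology	39.5	46.0	14.0	0.5	0
horse3	suspension_cytology	39.5	48.5	10.0	2.0	0
horse3	scrnaseq	71.3	16.9	11.0	0.8	0
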