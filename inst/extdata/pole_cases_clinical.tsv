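sample_id	pole_mutation	pole_tmb	age_years	histology	stage	grade	vital_status
P1	A456P	75.2	46	Endometrioid	III	2	Alive
P2	S297F	71.7	49	Endometrioid	I	3	Alive
P3	V411L	64.1	49	Endometrioid	III	3	Deceased
P4	P286R	28.6	46	Endometrioid	I	2	Alive
P5	P286R	21.6	49	Endometrioid	I	1	Alive
P6	V411L	5.8	51	Endometrioid	I	1	Alive
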