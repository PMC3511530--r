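tfr_name	tfr_locus	target_locus	target_product	separation_bp	represses_target
ActR	SCO5082	SCO5083	MFS transporter	110	TRUE
SGR3979	SGR3979	SGR3978	ABC transporter	144	TRUE
SCO3367	SCO3367	SCO3366	MFS transporter	158	TRUE
SGR5269	SGR5269	SGR5270	MFS transporter	212	FALSE
SGR3402	SGR3402	SGR3403	MFS transporter	601	FALSE
SCO4099	SCO4099	SCO4098	Acyltransferase (EC 2)	139	TRUE
SCO7222	SCO7222	SCO7223	Monooxygenase (EC 1)	146	TRUE
SGR6912	SGR6912	SGR6911	Glycosyl hydrolase (EC 3)	280	FALSE
AtrA	SCO4118	SCO4119	NADH dehydrogenase (EC 1)	425	FALSE
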