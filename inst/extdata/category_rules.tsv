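pattern	match_kind	major	ec_class	family	priority
major facilitator	keyword	MEMBRANE_TRANSPORTER	NA	MFS	10
MFS	keyword	MEMBRANE_TRANSPORTER	NA	MFS	11
MFS	name	MEMBRANE_TRANSPORTER	NA	MFS	12
ATP-binding cassette	keyword	MEMBRANE_TRANSPORTER	NA	ABC	20
ABC transporter	keyword	MEMBRANE_TRANSPORTER	NA	ABC	21
ABC	name	MEMBRANE_TRANSPORTER	NA	ABC	22
resistance-nodulation	keyword	MEMBRANE_TRANSPORTER	NA	RND	30
RND	keyword	MEMBRANE_TRANSPORTER	NA	RND	31
RND	name	MEMBRANE_TRANSPORTER	NA	RND	32
efflux	keyword	MEMBRANE_TRANSPORTER	NA	other	40
permease	keyword	MEMBRANE_TRANSPORTER	NA	other	41
antiporter	keyword	MEMBRANE_TRANSPORTER	NA	other	42
symporter	keyword	MEMBRANE_TRANSPORTER	NA	other	43
transporter	keyword	MEMBRANE_TRANSPORTER	NA	other	44
EC 1	keyword	ENZYME	1	NA	50
EC 2	keyword	ENZYME	2	NA	51
EC 3	keyword	ENZYME	3	NA	52
EC 4	keyword	ENZYME	4	NA	53
EC 5	keyword	ENZYME	5	NA	54
EC 6	keyword	ENZYME	6	NA	55
cl09931	accession	ENZYME	1	NA	60
NADB_Rossmann	name	ENZYME	1	NA	61
cl09933	accession	ENZYME	1	NA	62
ACAD	name	ENZYME	1	NA	63
oxidoreductase	keyword	ENZYME	1	NA	70
dehydrogenase	keyword	ENZYME	1	NA	71
monooxygenase	keyword	ENZYME	1	NA	72
oxygenase	keyword	ENZYME	1	NA	73
oxidase	keyword	ENZYME	1	NA	74
reductase	keyword	ENZYME	1	NA	75
transferase	keyword	ENZYME	2	NA	80
kinase	keyword	ENZYME	2	NA	81
glycosyl hydrolase	keyword	ENZYME	3	NA	90
hydrolase	keyword	ENZYME	3	NA	91
peptidase	keyword	ENZYME	3	NA	92
protease	keyword	ENZYME	3	NA	93
esterase	keyword	ENZYME	3	NA	94
lyase	keyword	ENZYME	4	NA	100
decarboxylase	keyword	ENZYME	4	NA	101
dehydratase	keyword	ENZYME	4	NA	102
isomerase	keyword	ENZYME	5	NA	110
epimerase	keyword	ENZYME	5	NA	111
ligase	keyword	ENZYME	6	NA	120
synthetase	keyword	ENZYME	6	NA	121
transmembrane	keyword	MEMBRANE_OTHER	NA	NA	130
integral membrane	keyword	MEMBRANE_OTHER	NA	NA	131
membrane protein	keyword	MEMBRANE_OTHER	NA	NA	132
transcriptional regulator	keyword	OTHER_PROTEIN	NA	NA	140
transcription factor	keyword	OTHER_PROTEIN	NA	NA	141
regulator	keyword	OTHER_PROTEIN	NA	NA	142
DNA-binding	keyword	OTHER_PROTEIN	NA	NA	143
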