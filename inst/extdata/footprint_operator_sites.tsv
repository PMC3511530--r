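tfr_name	site_index	site_seq
ActR	1	GAACGGGCCACCGTTT
ActR	2	CGCGACCACCGTTCCAT
ActR	3	AGAACGGTGGTCGTTCG
SGR3979	1	TGCGTAATGCTTACGCA
SGR3979	2	CGCGTATGGCATACGCA
SCO3367	1	ACTTGACGCCCGGCTAGT
SCO3367	2	ACTTGCCGGGCGGCAAGT
SGR5269	1	TTGCGCAGTGGGCAA
SGR5269	2	TTGCCCAGTGTGCAT
SCO4099	1	CACCTGTCGCACTAGTG
SCO7222	1	TGGAACGTCGTTCCA
SCO7222	2	TGGAACGACGTTCCA
SCO7222	3	TGGAACGCCGTTCCA
SGR6912	1	ACTAACCACTTAGT
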