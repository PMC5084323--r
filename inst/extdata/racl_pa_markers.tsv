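locus_id	sequence	t_f_present	t_m_present	a_f_present	a_m_present	discovered_in	forest5_affected
RaclCT014	TGCAGTGTCTCTGAGGGTTTACTGGTGATCCAGCGCATG	0.27	0.58	0.00	0.92	adult	TRUE
RaclCT015	TGCAGCATATGTGCGTACGGTCGGCGGGAAGGGGTTAAGCTATGTCCAGTGCCCTGCATG	0.00	0.58	0.09	0.94	adult	TRUE
RaclCT016	TGCAGCTCAGTATCTCCGGCCTCTGTCTGTCCTGTCCTTGACAGCATG	0.00	0.62	0.04	0.92	adult	TRUE
RaclCT017	TGCAGAAGTGCAGTGCATTGCTGTATGATTGGCCAAAGCATG	0.30	0.60	0.09	0.96	adult	TRUE
RaclCT018	TGCAGCAAGAGGTGAAAACAACCGCTGTTGGCAGCATG	0.00	1.00	0.04	0.89	tadpole	FALSE
RaclCT019	TGCAGTGCTTGAGATGGATCACACAGTGTGATCCATCTCAAAAACTGCGACTGTTGCATG	0.00	1.00	0.05	0.89	tadpole	FALSE
RaclCT020	TGCAGGCTGCAAAGAAGAAACGAGAAAGCTGCATG	0.00	1.00	0.13	0.94	tadpole	FALSE
RaclCT021	TGCAGCATTGCAGTGCATTGTTGTCTGATGATTGGGCAAGCATG	0.00	1.00	0.04	0.94	tadpole	FALSE
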