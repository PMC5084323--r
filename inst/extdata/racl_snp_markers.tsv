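locus_id	ref_sequence	alt_sequence	t_f_ref_hom	t_m_ref_hom	t_f_alt_hom	t_m_alt_hom	t_f_het	t_m_het	a_f_ref_hom	a_m_ref_hom	a_f_alt_hom	a_m_alt_hom	a_f_het	a_m_het	discovered_in	forest5_affected
RaclCT001	TGCAGCCAACATGTGTTTATGTGCTTTGTTCAGCATG	TGCAGCCAACATGTGTTTATGTACTTTGTTCAGCATG	1.00	0.00	0.00	0.08	0.00	0.92	1.00	0.00	0.00	0.02	0.00	0.98	both	FALSE
RaclCT002	TGCAGCGAGAACATTTCGGCATG	TGCAGCGAGAACATTTTGGCATG	1.00	0.00	0.00	0.00	0.00	1.00	1.00	0.04	0.00	0.00	0.00	0.96	both	FALSE
RaclCT003	TGCAGACAGTTGATGACTTCTGCGCACTGTGTCCTTCAGCATG	TGCAGACAGTTGATGACTTTTGCGCACTGTGTCCTTCAGCATG	1.00	0.00	0.00	0.23	0.00	0.77	1.00	0.06	0.00	0.11	0.00	0.83	both	FALSE
RaclCT004	TGCAGTAGGCATTGGTGATTCATTGATTGTTTTATGCATG	TGCAGTAGGCATTGGTGATTCATTAATTGTTTTATGCATG	0.92	0.00	0.00	0.00	0.08	1.00	0.96	0.13	0.00	0.02	0.04	0.85	both	FALSE
RaclCT005	TGCAGACAAACTCATGCTGTGTCTAATCACAGCACAGGTCAGAGTGGGGCATGTGCATG	TGCAGACAAACTCATGCTGTGTCTAATCACAGCACAGGTCAGAGTAGGGCATGTGCATG	0.75	0.00	0.00	0.08	0.25	0.92	0.91	0.07	0.00	0.04	0.09	0.89	adult	TRUE
RaclCT006	TGCAGTGTTATTGCATCATAGGAGCATG	TGCAGTGTTATTGCATTATAGGAGCATG	0.92	0.31	0.00	0.00	0.08	0.69	0.91	0.07	0.00	0.04	0.09	0.89	both	TRUE
RaclCT007	TGCAGCTCAGTCTCTCCGGCCTCTGTGTGTCCTGTCCTTGACAGCATG	TGCAGCTCAGTATCTCCGGCCTCTGTGTGTCCTGTCCTTGACAGCATG	1.00	0.38	0.00	0.00	0.00	0.62	0.96	0.07	0.00	0.13	0.04	0.80	both	TRUE
RaclCT008	TGCAGATGAGGATGTACTGGCTTCACTGGCTTCAATTACTGCATG	TGCAGATGAGGATGTACTGGCTTCACTGGCTTTAATTACTGCATG	0.92	0.00	0.00	0.00	0.08	1.00	0.87	0.09	0.00	0.04	0.13	0.87	both	FALSE
RaclCT009	TGCAGCTGGGTCTGATCCCACAAGATCCTTCATCGTCGCATG	TGCAGCTGGGTCTGATTCCACAAGATCCTTCATCGTCGCATG	1.00	0.38	0.00	0.00	0.00	0.62	0.91	0.06	0.04	0.13	0.04	0.81	both	TRUE
RaclCT010	TGCAGTTTTTTCTCACAATGCAGCAGCATG	TGCAGTTTTTTCTCACAATACAGCAGCATG	0.92	0.00	0.00	0.08	0.08	0.92	0.90	0.07	0.00	0.13	0.10	0.80	both	FALSE
RaclCT011	TGCAGCTCACTCTGTACAGATTCCCTGCATGAGATCGGAAGAGCGGTTCAGCAGGAATGCCGAGACCGA	TGCAGCTCACTCTCTACAGATTCCCTGCATGAGATCGGAAGAGCGGTTCAGCAGGAATGCCGAGACCGA	0.75	0.31	0.00	0.00	0.25	0.69	0.87	0.09	0.00	0.09	0.13	0.81	adult	TRUE
RaclCT012	TGCAGCCATGTGGCTAATTAGAAGGCTGGAGGCTGCAAGTTTCTAGGCATG	TGCAGCCATGTGACTAATTAGAAGGCTGGAGGCTGCAAGTTTCTAGGCATG	0.92	0.00	0.00	0.08	0.08	0.92	0.74	0.04	0.00	0.11	0.24	0.85	tadpole	FALSE
RaclCT013	TGCAGCTGTTTTTGCCACAAAGTGCATG	TGCAGCTTTTTTTGCCACAAAGTGCATG	0.92	0.00	0.00	0.15	0.08	0.85	0.61	0.02	0.13	0.15	0.26	0.83	tadpole	FALSE
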