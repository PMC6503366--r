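#N=22885
#n=1413
#total_pathways=242
pathway	m	M	pathway_id
Complement and coagulation cascades	51	235	ko04610
Staphylococcus aureus infection	33	181	ko05150
Hematopoietic cell lineage	30	212	ko04640
Bile secretion	28	192	ko04976
Cytokine-cytokine receptor interaction	46	395	ko04060
DNA replication	12	51	ko03030
Systemic lupus erythematosus	31	241	ko05322
Axon guidance	44	403	ko04360
Pertussis	23	177	ko05133
Cell cycle	31	273	ko04110
Vitamin digestion and absorption	13	78	ko04977
Steroid biosynthesis	10	54	ko00100
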