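label	or	or_lci	or_uci	pvalue
inferior_temporal_TH	0.1954	0.0584	0.6538	0.008
lateral_occipital_TH	0.1922	0.0648	0.5698	0.0029
lateral_orbitofrontal_TH	0.0714	0.0156	0.3277	0.0007
caudal_anterior_cingulate_TH	0.4266	0.1916	0.9500	0.037
frontal_pole_TH	0.4073	0.1720	0.9620	0.0406
fusiform_TH	0.0933	0.0114	0.7662	0.0273
pars_orbitalis_TH	0.1401	0.0280	0.6827	0.0149
pars_triangularis_TH	0.2053	0.0457	0.9214	0.0387
lateral_orbitofrontal_TH_adj	0.0750	0.0088	0.6368	0.0176
pericalcarine_TH_adj	25.1309	1.9890	317.5326	0.0127
lingual_SA	1.0004	1.0001	1.0007	0.0086
parahippocampal_SA	1.0023	1.0003	1.0043	0.0226
pericalcarine_SA	1.0005	1.0001	1.0010	0.0203
lingual_SA_adj	1.0005	1.0001	1.0009	0.0272
middle_temporal_SA_adj	1.0009	1.0003	1.0016	0.0037
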