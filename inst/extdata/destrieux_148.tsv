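roi	hemisphere	base_label	lobe
lh_G_and_S_frontomargin	lh	G_and_S_frontomargin	frontal
lh_G_and_S_occipital_inf	lh	G_and_S_occipital_inf	occipital
lh_G_and_S_paracentral	lh	G_and_S_paracentral	frontal
lh_G_and_S_subcentral	lh	G_and_S_subcentral	frontal
lh_G_and_S_transv_frontopol	lh	G_and_S_transv_frontopol	frontal
lh_G_and_S_cingul-Ant	lh	G_and_S_cingul-Ant	limbic
lh_G_and_S_cingul-Mid-Ant	lh	G_and_S_cingul-Mid-Ant	limbic
lh_G_and_S_cingul-Mid-Post	lh	G_and_S_cingul-Mid-Post	limbic
lh_G_cingul-Post-dorsal	lh	G_cingul-Post-dorsal	limbic
lh_G_cingul-Post-ventral	lh	G_cingul-Post-ventral	limbic
lh_G_cuneus	lh	G_cuneus	occipital
lh_G_front_inf-Opercular	lh	G_front_inf-Opercular	frontal
lh_G_front_inf-Orbital	lh	G_front_inf-Orbital	frontal
lh_G_front_inf-Triangul	lh	G_front_inf-Triangul	frontal
lh_G_front_middle	lh	G_front_middle	frontal
lh_G_front_sup	lh	G_front_sup	frontal
lh_G_Ins_lg_and_S_cent_ins	lh	G_Ins_lg_and_S_cent_ins	insula
lh_G_insular_short	lh	G_insular_short	insula
lh_G_occipital_middle	lh	G_occipital_middle	occipital
lh_G_occipital_sup	lh	G_occipital_sup	occipital
lh_G_oc-temp_lat-fusifor	lh	G_oc-temp_lat-fusifor	temporal
lh_G_oc-temp_med-Lingual	lh	G_oc-temp_med-Lingual	occipital
lh_G_oc-temp_med-Parahip	lh	G_oc-temp_med-Parahip	limbic
lh_G_orbital	lh	G_orbital	frontal
lh_G_pariet_inf-Angular	lh	G_pariet_inf-Angular	parietal
lh_G_pariet_inf-Supramar	lh	G_pariet_inf-Supramar	parietal
lh_G_parietal_sup	lh	G_parietal_sup	parietal
lh_G_postcentral	lh	G_postcentral	parietal
lh_G_precentral	lh	G_precentral	frontal
lh_G_precuneus	lh	G_precuneus	parietal
lh_G_rectus	lh	G_rectus	frontal
lh_G_subcallosal	lh	G_subcallosal	limbic
lh_G_temp_sup-G_T_transv	lh	G_temp_sup-G_T_transv	temporal
lh_G_temp_sup-Lateral	lh	G_temp_sup-Lateral	temporal
lh_G_temp_sup-Plan_polar	lh	G_temp_sup-Plan_polar	temporal
lh_G_temp_sup-Plan_tempo	lh	G_temp_sup-Plan_tempo	temporal
lh_G_temporal_inf	lh	G_temporal_inf	temporal
lh_G_temporal_middle	lh	G_temporal_middle	temporal
lh_Lat_Fis-ant-Horizont	lh	Lat_Fis-ant-Horizont	frontal
lh_Lat_Fis-ant-Vertical	lh	Lat_Fis-ant-Vertical	frontal
lh_Lat_Fis-post	lh	Lat_Fis-post	temporal
lh_Pole_occipital	lh	Pole_occipital	occipital
lh_Pole_temporal	lh	Pole_temporal	temporal
lh_S_calcarine	lh	S_calcarine	occipital
lh_S_central	lh	S_central	frontal
lh_S_cingul-Marginalis	lh	S_cingul-Marginalis	limbic
lh_S_circular_insula_ant	lh	S_circular_insula_ant	insula
lh_S_circular_insula_inf	lh	S_circular_insula_inf	insula
lh_S_circular_insula_sup	lh	S_circular_insula_sup	insula
lh_S_collat_transv_ant	lh	S_collat_transv_ant	temporal
lh_S_collat_transv_post	lh	S_collat_transv_post	occipital
lh_S_front_inf	lh	S_front_inf	frontal
lh_S_front_middle	lh	S_front_middle	frontal
lh_S_front_sup	lh	S_front_sup	frontal
lh_S_interm_prim-Jensen	lh	S_interm_prim-Jensen	parietal
lh_S_intrapariet_and_P_trans	lh	S_intrapariet_and_P_trans	parietal
lh_S_oc_middle_and_Lunatus	lh	S_oc_middle_and_Lunatus	occipital
lh_S_oc_sup_and_transversal	lh	S_oc_sup_and_transversal	occipital
lh_S_occipital_ant	lh	S_occipital_ant	occipital
lh_S_oc-temp_lat	lh	S_oc-temp_lat	temporal
lh_S_oc-temp_med_and_Lingual	lh	S_oc-temp_med_and_Lingual	temporal
lh_S_orbital_lateral	lh	S_orbital_lateral	frontal
lh_S_orbital_med-olfact	lh	S_orbital_med-olfact	frontal
lh_S_orbital-H_Shaped	lh	S_orbital-H_Shaped	frontal
lh_S_parieto_occipital	lh	S_parieto_occipital	parietal
lh_S_pericallosal	lh	S_pericallosal	limbic
lh_S_postcentral	lh	S_postcentral	parietal
lh_S_precentral-inf-part	lh	S_precentral-inf-part	frontal
lh_S_precentral-sup-part	lh	S_precentral-sup-part	frontal
lh_S_suborbital	lh	S_suborbital	frontal
lh_S_subparietal	lh	S_subparietal	parietal
lh_S_temporal_inf	lh	S_temporal_inf	temporal
lh_S_temporal_sup	lh	S_temporal_sup	temporal
lh_S_temporal_transverse	lh	S_temporal_transverse	temporal
rh_G_and_S_frontomargin	rh	G_and_S_frontomargin	frontal
rh_G_and_S_occipital_inf	rh	G_and_S_occipital_inf	occipital
rh_G_and_S_paracentral	rh	G_and_S_paracentral	frontal
rh_G_and_S_subcentral	rh	G_and_S_subcentral	frontal
rh_G_and_S_transv_frontopol	rh	G_and_S_transv_frontopol	frontal
rh_G_and_S_cingul-Ant	rh	G_and_S_cingul-Ant	limbic
rh_G_and_S_cingul-Mid-Ant	rh	G_and_S_cingul-Mid-Ant	limbic
rh_G_and_S_cingul-Mid-Post	rh	G_and_S_cingul-Mid-Post	limbic
rh_G_cingul-Post-dorsal	rh	G_cingul-Post-dorsal	limbic
rh_G_cingul-Post-ventral	rh	G_cingul-Post-ventral	limbic
rh_G_cuneus	rh	G_cuneus	occipital
rh_G_front_inf-Opercular	rh	G_front_inf-Opercular	frontal
rh_G_front_inf-Orbital	rh	G_front_inf-Orbital	frontal
rh_G_front_inf-Triangul	rh	G_front_inf-Triangul	frontal
rh_G_front_middle	rh	G_front_middle	frontal
rh_G_front_sup	rh	G_front_sup	frontal
rh_G_Ins_lg_and_S_cent_ins	rh	G_Ins_lg_and_S_cent_ins	insula
rh_G_insular_short	rh	G_insular_short	insula
rh_G_occipital_middle	rh	G_occipital_middle	occipital
rh_G_occipital_sup	rh	G_occipital_sup	occipital
rh_G_oc-temp_lat-fusifor	rh	G_oc-temp_lat-fusifor	temporal
rh_G_oc-temp_med-Lingual	rh	G_oc-temp_med-Lingual	occipital
rh_G_oc-temp_med-Parahip	rh	G_oc-temp_med-Parahip	limbic
rh_G_orbital	rh	G_orbital	frontal
rh_G_pariet_inf-Angular	rh	G_pariet_inf-Angular	parietal
rh_G_pariet_inf-Supramar	rh	G_pariet_inf-Supramar	parietal
rh_G_parietal_sup	rh	G_parietal_sup	parietal
rh_G_postcentral	rh	G_postcentral	parietal
rh_G_precentral	rh	G_precentral	frontal
rh_G_precuneus	rh	G_precuneus	parietal
rh_G_rectus	rh	G_rectus	frontal
rh_G_subcallosal	rh	G_subcallosal	limbic
rh_G_temp_sup-G_T_transv	rh	G_temp_sup-G_T_transv	temporal
rh_G_temp_sup-Lateral	rh	G_temp_sup-Lateral	temporal
rh_G_temp_sup-Plan_polar	rh	G_temp_sup-Plan_polar	temporal
rh_G_temp_sup-Plan_tempo	rh	G_temp_sup-Plan_tempo	temporal
rh_G_temporal_inf	rh	G_temporal_inf	temporal
rh_G_temporal_middle	rh	G_temporal_middle	temporal
rh_Lat_Fis-ant-Horizont	rh	Lat_Fis-ant-Horizont	frontal
rh_Lat_Fis-ant-Vertical	rh	Lat_Fis-ant-Vertical	frontal
rh_Lat_Fis-post	rh	Lat_Fis-post	temporal
rh_Pole_occipital	rh	Pole_occipital	occipital
rh_Pole_temporal	rh	Pole_temporal	temporal
rh_S_calcarine	rh	S_calcarine	occipital
rh_S_central	rh	S_central	frontal
rh_S_cingul-Marginalis	rh	S_cingul-Marginalis	limbic
rh_S_circular_insula_ant	rh	S_circular_insula_ant	insula
rh_S_circular_insula_inf	rh	S_circular_insula_inf	insula
rh_S_circular_insula_sup	rh	S_circular_insula_sup	insula
rh_S_collat_transv_ant	rh	S_collat_transv_ant	temporal
rh_S_collat_transv_post	rh	S_collat_transv_post	occipital
rh_S_front_inf	rh	S_front_inf	frontal
rh_S_front_middle	rh	S_front_middle	frontal
rh_S_front_sup	rh	S_front_sup	frontal
rh_S_interm_prim-Jensen	rh	S_interm_prim-Jensen	parietal
rh_S_intrapariet_and_P_trans	rh	S_intrapariet_and_P_trans	parietal
rh_S_oc_middle_and_Lunatus	rh	S_oc_middle_and_Lunatus	occipital
rh_S_oc_sup_and_transversal	rh	S_oc_sup_and_transversal	occipital
rh_S_occipital_ant	rh	S_occipital_ant	occipital
rh_S_oc-temp_lat	rh	S_oc-temp_lat	temporal
rh_S_oc-temp_med_and_Lingual	rh	S_oc-temp_med_and_Lingual	temporal
rh_S_orbital_lateral	rh	S_orbital_lateral	frontal
rh_S_orbital_med-olfact	rh	S_orbital_med-olfact	frontal
rh_S_orbital-H_Shaped	rh	S_orbital-H_Shaped	frontal
rh_S_parieto_occipital	rh	S_parieto_occipital	parietal
rh_S_pericallosal	rh	S_pericallosal	limbic
rh_S_postcentral	rh	S_postcentral	parietal
rh_S_precentral-inf-part	rh	S_precentral-inf-part	frontal
rh_S_precentral-sup-part	rh	S_precentral-sup-part	frontal
rh_S_suborbital	rh	S_suborbital	frontal
rh_S_subparietal	rh	S_subparietal	parietal
rh_S_temporal_inf	rh	S_temporal_inf	temporal
rh_S_temporal_sup	rh	S_temporal_sup	temporal
rh_S_temporal_transverse	rh	S_temporal_transverse	temporal
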