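quantity	value
model_a_deg_up	1714
model_a_deg_down	1757
model_a_deg_total	3471
chirp_peaks	11928
rdg_count	1190
rig_count	2281
rdg_pct	34.28
rig_pct	65.72
up_pct	49.38
down_pct	50.62
tf_rdgs	112
cofactor_rdgs	82
tf_coherent	33
cofactor_coherent	21
common_degs	1416
rdg_tfs	18
tf_predicted_rdg	478
tf_predicted_rig	792
tf_predicted_total	1270
tf_direct_targets	1702
common_direct_model_a	377
comm_dgs	160
model_b_lnc_degs	4694
model_b_tf_degs	4677
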