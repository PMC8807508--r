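# Reference adult physiology, ICRP-style reference individuals (age ~30 y).
# Organ blood flows are blood flows in L/h; cardiac output is defined as the
# sum of all arterial draws (systemic organs + hepatic artery) so that venous
# return balances exactly. Liver receives hepatic artery + portal vein.
# version: 1
key	female	male
body_weight_kg	60.0	73.0
hematocrit_frac	0.40	0.43
gfr_L_per_h	7.2	7.8
volume_lung_L	0.95	1.10
volume_brain_L	1.30	1.45
volume_heart_L	0.25	0.33
volume_kidney_L	0.30	0.36
volume_liver_L	1.40	1.65
volume_gut_wall_L	1.10	1.20
volume_stomach_L	0.15	0.16
volume_spleen_L	0.15	0.18
volume_pancreas_L	0.12	0.14
volume_muscle_L	17.5	29.0
volume_adipose_L	19.0	14.5
volume_skin_L	2.30	3.00
volume_bone_L	7.80	9.80
volume_gonads_L	0.011	0.035
volume_arterial_blood_L	1.30	1.55
volume_venous_blood_L	2.90	3.45
volume_portal_blood_L	0.30	0.35
volume_gut_lumen_L	0.25	0.25
flow_brain_L_per_h	42	46
flow_heart_L_per_h	15	18
flow_kidney_L_per_h	66	74
flow_muscle_L_per_h	45	60
flow_adipose_L_per_h	18	16
flow_skin_L_per_h	18	20
flow_bone_L_per_h	12	14
flow_gonads_L_per_h	1	1
flow_stomach_L_per_h	3	3.5
flow_spleen_L_per_h	5	6
flow_pancreas_L_per_h	3	3.5
flow_gut_wall_L_per_h	36	40
flow_hepatic_artery_L_per_h	24	27
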