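# Tissue conductivities (S/m) for the 5-layer (7-compartment) and 3-layer
# model classes.  Editable: rows are <set>	<tissue>	<sigma>.
# The cerebellum entry of the VWB set is a 40/60 weighted average of its
# GM and WM values; eye entries reuse the CSF value of each set.
# Extra compartments (cerebellum/ventricles/eyes) are only used when the
# optional extra interior shell is enabled.
set	tissue	sigma
VWB7	skin	0.430
VWB7	skull	0.010
VWB7	csf	1.790
VWB7	gm	0.330
VWB7	wm	0.140
VWB7	cerebellum	0.216
VWB7	ventricles	1.790
VWB7	eyes	1.790
ITIS7	skin	0.147
ITIS7	skull	0.0179
ITIS7	csf	1.880
ITIS7	gm	0.419
ITIS7	wm	0.348
ITIS7	cerebellum	0.577
ITIS7	ventricles	1.880
ITIS7	eyes	1.880
SIMNIBS7	skin	0.465
SIMNIBS7	skull	0.010
SIMNIBS7	csf	1.654
SIMNIBS7	gm	0.275
SIMNIBS7	wm	0.126
SIMNIBS7	cerebellum	0.126
SIMNIBS7	ventricles	1.654
SIMNIBS7	eyes	1.654
VWB3	skin	0.430
VWB3	skull	0.010
VWB3	brain	0.330
ITIS3	skin	0.147
ITIS3	skull	0.0179
ITIS3	brain	0.375
SIMNIBS3	skin	0.465
SIMNIBS3	skull	0.010
SIMNIBS3	brain	0.330
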