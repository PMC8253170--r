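model	type	k_min	k_max	k_dif	elements_sheath	elements_spike	biomass	time_step	notes
APSIM-Wheat-v7.5	constant	0.50	0.50	NA	no	no	RUE/TE	daily
APSIM-Wheat-2018	constant	0.50	0.60	NA	no	no	RUE	daily	K increases from stem extension to flag leaf ligule (Haun-stage variant)
AFRCWHEAT2	constant	0.44	0.44	NA	yes	no	P-R	hourly
CropSyst	constant	0.45	0.45	NA	no	no	RUE/TE	daily
DAISY	constant	0.60	0.60	NA	yes	no	GP	hourly
DSSAT-CERES-Wheat	constant	0.59	0.59	NA	no	no	RUE	daily
DSSAT-CROPSIM	constant	0.65	0.65	NA	yes	yes	RUE(PAR)	daily
EPIC	constant	0.65	0.65	NA	no	no	RUE	daily
FASSET	constant	0.44	0.44	NA	no	no	RUE	daily
GLAM	constant	0.50	0.50	NA	yes	no	TE	daily
HERMES-MONICA	constant	0.80	0.80	NA	no	no	P-R	daily
InfoCrop	constant	0.60	0.60	NA	yes	yes	RUE	daily
LINTUL	constant	0.60	0.60	NA	no	no	RUE	daily
LPjML	constant	0.50	0.50	NA	no	no	P-R	daily
MCWLA	constant	0.50	0.50	NA	yes	no	P-R	daily
NWheat	constant	0.60	0.70	NA	no	no	RUE	daily	K 0.6 before anthesis and 0.7 after
SALUS	constant	0.37	0.67	NA	no	no	RUE	daily	K from plant density and row spacing; range for d 100-400 m-2, s 0.15-0.35 m
Sirius-v99	constant	0.45	0.45	NA	yes	no	RUE(f)	daily
SiriusQuality	constant	0.45	0.45	NA	yes	no	RUE(f)	daily
SSM-Wheat	constant	0.65	0.65	NA	no	no	RUE	daily
STICS-v9	constant	0.50	0.50	NA	yes	no	RUE(PAR)	daily
SUCROS97	spherical	NA	NA	0.6	no	no	P-R	gauss3	clumped spherical direct K
SPASS	spherical	NA	NA	0.8	yes	yes	P-R	hourly	unclumped spherical direct K
WOFOST	spherical	NA	NA	0.6	no	no	P-R	gauss3	clumped spherical direct K
WHEATGROW	spherical	NA	NA	0.67	no	no	P-R	hourly	clumped spherical direct K
GECROS	average	NA	NA	NA	yes	yes	P-R	gauss5	average-inclination projection; diffuse K from overcast-sky class weighting
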