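parameter	symbol	units	printed_factor_disease	printed_factor_treated	direction
Pulmonary vascular resistance	PVR	mmHg s/ml	1.96	1.96	up
Pulmonary artery compliance	CPA	ul/mmHg	0.70	0.70	down
Fibrosis (collagen contribution)	Con_collagen	normalized force	1.69	1.69	up
Maximum force (myosin head stiffness)	k_stiff2	MPa/um	0.46	0.22	down
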