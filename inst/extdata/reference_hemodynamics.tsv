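parameter	units	control	disease	disease_treated	printed_fold_disease	printed_fold_treated	group
RV systolic pressure	mmHg	20.9	42.9	NA	+1.10	NA	hemodynamics
RV diastolic pressure	mmHg	2.4	6.7	NA	+1.80	NA	hemodynamics
Arterial elastance (Ea)	mmHg/ul	0.91	2.75	NA	+3.00	NA	pulmonary vascular indices
Cardiac output (normalized)	-	1.0	0.44-0.70	0.78	-0.30--0.56	-0.20	right ventricular indices
Ejection fraction (EF)	%	69.6	39.4	NA	-0.43	NA	right ventricular indices
Fractional shortening (FS)	%	46.1	20.1	36.8	-0.56	-0.22	right ventricular indices (not simulated)
Contractility index	-	129.1	56.4	NA	-0.56	NA	right ventricular indices (not simulated)
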