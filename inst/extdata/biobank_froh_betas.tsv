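trait	beta_minimal	beta_sociodemographic
age_at_first_intercourse	4.355	3.479
grip_strength	-1.706	-1.368
height	-1.821	-1.150
fluid_intelligence	-3.455	-3.414
fev1	-2.677	-2.791
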