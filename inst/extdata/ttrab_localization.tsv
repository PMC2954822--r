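rab	category	conserved	cloned
TtRabD5	Parasomal sacs	FALSE	TRUE
TtRab21	Endocytic vesicles	TRUE	TRUE
TtRab22A	Endocytic vesicles	TRUE	TRUE
TtRabD4	Endocytic vesicles	FALSE	TRUE
TtRabD28	Endocytic vesicles	FALSE	TRUE
TtRab11A	Posterior (recycling?) endosomes	TRUE	TRUE
TtRabD35	Posterior (recycling?) endosomes	FALSE	TRUE
TtRabD27	Posterior (recycling?) endosomes	FALSE	TRUE
TtRabD24	Posterior (recycling?) endosomes	FALSE	TRUE
TtRab7	Lysosomes/phagosomes	TRUE	TRUE
TtRab11B	Oral apparatus	TRUE	TRUE
TtRab4B	Oral apparatus	TRUE	TRUE
TtRabD34	Oral apparatus	FALSE	TRUE
TtRabD32	Oral apparatus	FALSE	TRUE
TtRabD17	Oral apparatus	FALSE	TRUE
TtRab32	All phagosomes	TRUE	TRUE
TtRabD26	Selected phagosomes	FALSE	TRUE
TtRabD25	Selected phagosomes	FALSE	TRUE
TtRabD13	Selected phagosomes	FALSE	TRUE
TtRabD17	Selected phagosomes	FALSE	TRUE
TtRabD3	Selected phagosomes	FALSE	TRUE
TtRabD15	Selected phagosomes	FALSE	TRUE
TtRabD19	Cytoproct-localized phagosomes	FALSE	TRUE
TtRabD20	Cytoproct-localized phagosomes	FALSE	TRUE
TtRabD30	Cytoproct-localized phagosomes	FALSE	TRUE
TtRab4A	Cytoproct region	TRUE	TRUE
TtRabD39	Cytoproct region	FALSE	TRUE
TtRabD2	Contractile vacuole Rabs	FALSE	TRUE
TtRabD10	Contractile vacuole Rabs	FALSE	TRUE
TtRabD14	Contractile vacuole Rabs	FALSE	TRUE
TtRab1	ER-to-Golgi	TRUE	TRUE
TtRabD33	ER-to-Golgi	FALSE	TRUE
TtRab6C	Golgi	TRUE	TRUE
TtRab6D	Golgi	TRUE	TRUE
TtRab6B	Golgi	TRUE	TRUE
TtRab6A	Golgi	TRUE	TRUE
TtRabD38	Golgi	FALSE	TRUE
TtRabD41	Dense core granule docking	FALSE	TRUE
TtRabD23	Basal bodies	FALSE	TRUE
TtRabD36	Cortical cytoskeleton	FALSE	TRUE
TtRabD40	Cortical cytoskeleton	FALSE	TRUE
TtRab31	Cortical cytoskeleton	TRUE	TRUE
TtRabD18	Plasma membrane vicinity	FALSE	TRUE
TtRabD29	Plasma membrane vicinity	FALSE	TRUE
TtRabD31	Nuclear envelope	FALSE	TRUE
TtRabD6	Indeterminate structures	FALSE	TRUE
TtRabD7	Indeterminate structures	FALSE	TRUE
TtRabD9	Indeterminate structures	FALSE	TRUE
TtRabD11	Indeterminate structures	FALSE	TRUE
TtRabD21	Indeterminate structures	FALSE	TRUE
TtRabD12	Indeterminate structures	FALSE	TRUE
TtRabD16	Indeterminate structures	FALSE	TRUE
TtRabD1	Indeterminate structures	FALSE	TRUE
TtRab11C	Not cloned	TRUE	FALSE
TtRabD8	Not cloned	FALSE	FALSE
TtRabD22	Not cloned	FALSE	FALSE
TtRabD37	Not cloned	FALSE	FALSE
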