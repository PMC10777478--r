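Product_ID	Product_Type	Ingredient_Name	Ingredient_Function	Concentration_mg_ml
EL-0001	E-liquid	Propylene glycol	carrier/solvent	512.3
EL-0001	E-liquid	Glycerol	carrier/solvent	401.8
EL-0001	E-liquid	Vanillin	flavour and/or taste enhancer	0.95
EL-0001	E-liquid	Ethyl vanillin	flavour and/or taste enhancer	1.15
EL-0001	E-liquid	Nicotine	nicotine	18.0
EL-0001	E-liquid	Benzoic acid	additive	11.2
EL-0002	E-liquid	Propylene glycol	carrier/solvent	498.0
EL-0002	E-liquid	L-menthol	flavour and/or taste enhancer	2.4
EL-0002	E-liquid	Menthol	flavour and/or taste enhancer	0.6
EL-0002	E-liquid	Eucalyptol	flavour and/or taste enhancer	0.3
EL-0003	E-liquid	Propylene glycol	carrier/solvent	505.1
EL-0003	E-liquid	Vanillin propylene glycol acetal	flavour and/or taste enhancer	0.4
EL-0003	E-liquid	Piperonal	flavour and/or taste enhancer	0.14
EL-0003	E-liquid	Citric acid monohydrate	pH modifier	0.9
DP-0001	Disposable e-cigarette	Glycerol	carrier/solvent	460.2
DP-0001	Disposable e-cigarette	Ethyl butyrate	flavour and/or taste enhancer	0.79
DP-0001	Disposable e-cigarette	Ethyl hexanoate	flavour and/or taste enhancer	0.15
DP-0001	Disposable e-cigarette	Nicotine	nicotine	20.0
DV-0001	Device	Stainless steel	hardware	NA
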