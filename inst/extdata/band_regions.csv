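name,lo,hi
fatty_acid_carbonyl,1680,1770
lipid_broad,1600,1760
amide_I,1600,1700
amide_II,1519,1544
phosphate_PO2,1200,1230
carbohydrate,1000,1300
carbohydrate_alt_1250,1000,1250
carbohydrate_alt_1200,1000,1200
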