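compound,class,peak_cm1,weight,tol_cm1
PHA,storage,1740,1,8
PHA,storage,1165,1,8
PHA,storage,1100,1,8
PHB,storage,1722,1,8
PHB,storage,1279,1,8
PHB,storage,1228,1,8
PHB,storage,1057,1,8
glycogen,storage,1152,1,8
glycogen,storage,1080,1,8
glycogen,storage,1022,1,8
polyphosphate,storage,1265,1,8
polyphosphate,storage,1150,1,8
polyphosphate,storage,1100,1,8
trehalose,general_stress,1150,1,8
trehalose,general_stress,1105,1,8
trehalose,general_stress,1055,1,8
proline,general_stress,1620,1,8
proline,general_stress,1551,1,8
proline,general_stress,1403,1,8
glutamate,general_stress,1560,1,8
glutamate,general_stress,1404,1,8
glutamate,general_stress,1350,1,8
mannitol,osmolyte,1082,1,8
mannitol,osmolyte,1020,1,8
mannitol,osmolyte,929,1,8
ectoine,osmolyte,1622,1,8
ectoine,osmolyte,1577,1,8
ectoine,osmolyte,1395,1,8
glycine betaine,osmolyte,1610,1,8
glycine betaine,osmolyte,1479,1,8
glycine betaine,osmolyte,1394,1,8
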