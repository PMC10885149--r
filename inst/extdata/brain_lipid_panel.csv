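lipid_class,name,alias,reference_mass,tof_mz,orbitrap_mz,flag
CerP,CerP(d18:1/16:0),,617.4784,616.453,616.4712,
CerP,CerP(d18:1/18:0),,645.5097,644.421,644.5025,
CerP,CerP(d18:1/20:0),,673.5410,672.483,672.5339,
PE-Cer,PE-Cer(36:1),Cer-PE(36:1),688.5519,687.496,687.5443,
PE-Cer,PE-Cer(38:1),Cer-PE(38:1),716.5832,715.565,715.5757,
PE-Cer,PE-Cer(40:1),Cer-PE(40:1),744.6145,743.509,743.6070,
GM3,GM3(d18:1/18:0),,1180.7445,1179.599,1179.7366,
GM3,GM3(d18:1/20:0),,1208.7758,120.763,1207.7683,
GM2,GM2(d18:1/18:0),,1383.8238,1382.717,1382.8153,
GM2,GM2(d18:1/20:0),,1411.8551,1410.756,1410.8457,
GM1,GM1(d18:1/18:0),,1545.8767,1544.733,1544.8679,
GM1,GM1(d18:1/20:0),,1573.9080,1572.818,1572.8992,
HexCer,HexCer(d18:1/12:0),,643.5023,642.394,,
HexCer,HexCer(d18:1/14:0),HexCer(18:1/14:0),671.5336,670.464,,
CPA,CPA(18:0),LPA(18:0),420.2641,419.251,419.2569,
PA,PA(16:0/16:0),,648.4730,647.445,,
PA,PA(16:0/18:1),,672.4730,673.441,673.4813,excluded
PA,PA(18:0/22:6),,748.5043,747.469,747.4970,
LPE,LPE(18:0),PE(18:0),481.3168,480.245,480.3096,
LPE,LPE(22:6),PE(22:6),525.2855,524.247,524.2785,
PE,PE(18:1/18:0),PE (18:1/18:0),745.5622,744.523,744.5548,
PE,PE(18:1/20:0),,773.5935,772.467,,
PE,PE(P-18:0/20:4),,751.5516,750.525,750.5444,
PE,PE(18:0/20:4),,767.5465,766.559,766.5395,
PE,PE(16:0/22:6),,763.5152,762.403,762.5078,
PE,PE(P-18:0/22:6),,775.5516,77.447,774.5444,
PE,PE(18:0/22:6),,791.5465,790.449,790.5392,
LPI,LPI(16:0),PI(16:0),572.2962,571.242,,
LPI,LPI(18:0),PI(18:0),600.3275,599.274,599.3203,
LPI,LPI(20:4),PI(20:4),620.1377,619.258,619.2890,theor_typo
PI,PI(16:0/20:4),,858.5258,857.414,857.5185,
PI,PI(18:0/20:4),PI (18:0/20:4),886.5571,885.468,,
ST,ST(d18:1/22:0),,863.6156,862.513,862.6080,
ST,ST(d18:1/22:0(2OH)),,879.6106,878.539,878.6033,
ST,ST(d18:1/24:1),,889.6313,88.854,888.6238,
ST,ST(d18:1/24:0),,891.6469,890.559,890.6398,
ST,ST(d18:1/24:1(2OH)),,905.6262,904.543,904.6187,
ST,ST(d18:1/24:0(2OH)),,907.6419,90.657,906.6346,
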