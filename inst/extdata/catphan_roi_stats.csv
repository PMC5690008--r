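material,recon,mean,sd,dhu,cnr
Air1,pCT,68,11,NA,80.7
Air2,pCT,68,11,NA,80.7
PMP,pCT,853,7,NA,27.0
LDPE,pCT,940,7,NA,16.9
Polystyrene,pCT,994,7,NA,12.7
Acrylic,pCT,1145,9,NA,2.2
Delrin,pCT,1363,9,NA,21.3
Teflon,pCT,1936,10,NA,66.8
Air1,raw,302,21,234,26.7
Air2,raw,294,23,226,25.8
PMP,raw,834,16,-19,8.3
LDPE,raw,901,16,-39,5.5
Polystyrene,raw,939,17,-55,3.8
Acrylic,raw,1043,19,-102,0.6
Delrin,raw,1199,17,-164,7.1
Teflon,raw,1621,21,-315,21.7
Air1,corrected,185,22,117,33.9
Air2,corrected,184,31,116,26.2
PMP,corrected,877,17,24,9.9
LDPE,corrected,958,17,18,6.6
Polystyrene,corrected,1005,18,11,4.4
Acrylic,corrected,1119,17,-26,0.2
Delrin,corrected,1327,18,-36,8.8
Teflon,corrected,1872,20,-64,28.8
Air1,varian,27,6,-41,34.2
Air2,varian,32,14,-36,31.4
PMP,varian,785,30,-68,6.8
LDPE,varian,881,34,-59,4.2
Polystyrene,varian,940,32,-54,3.0
Acrylic,varian,1105,33,-40,0.7
Delrin,varian,1321,41,-42,4.9
Teflon,varian,1965,37,29,18.7
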