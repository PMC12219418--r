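service,AL,FO,GL,WA,CL,UL
FP,877.14,319.90,392.13,825.54,0.00,0.00
MP,412.77,732.67,577.88,237.34,0.00,0.00
WS,20.64,381.81,319.90,8554.70,0.00,0.00
GR,691.39,2425.04,2032.90,794.59,0.00,20.64
CR,371.49,7254.47,5376.36,2363.12,0.00,0.00
AP,103.19,2053.54,1774.92,5727.21,0.00,103.19
WR,278.62,3622.07,3941.97,105504.52,0.00,30.96
SR,1062.89,2951.32,2476.63,959.69,0.00,20.64
NC,123.83,227.02,185.75,72.24,0.00,0.00
BM,134.15,2683.02,2249.61,2631.42,0.00,20.64
AL_s,61.92,1176.40,990.65,1950.35,0.00,10.32
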