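class,AL,FO,GL,WA,CL,UL
AL,0.833050,0.031947,0.069884,0.004447,0.060514,0.000158
FO,0.032090,0.911820,0.044205,0.001152,0.010618,0.000114
GL,0.094196,0.052104,0.824330,0.001852,0.027295,0.000224
WA,0.190143,0.030562,0.045479,0.655013,0.073460,0.005342
CL,0.089626,0.008296,0.010054,0.001813,0.889800,0.000411
UL,0.241284,0.032035,0.084214,0.058920,0.142172,0.441375
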