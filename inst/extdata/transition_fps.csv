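class,AL,FO,GL,WA,CL,UL
AL,0.870611,0.033387,0.073035,0.004648,0.018154,0.000165
FO,0.032169,0.914079,0.044315,0.001155,0.008168,0.000114
GL,0.094806,0.052441,0.829667,0.001864,0.020996,0.000225
WA,0.190143,0.030562,0.045479,0.655013,0.073460,0.005342
CL,0.194190,0.013099,0.015873,0.002862,0.773619,0.000357
UL,0.381921,0.028031,0.073689,0.051556,0.078593,0.386210
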