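class,AL,FO,GL,WA,CL,UL
AL,0.833050,0.031947,0.069884,0.004447,0.060514,0.000158
FO,0.032169,0.914079,0.044315,0.001155,0.008168,0.000114
GL,0.094806,0.052441,0.829667,0.001864,0.020996,0.000225
WA,0.190143,0.030562,0.045479,0.655013,0.073460,0.005342
CL,0.149377,0.013827,0.016756,0.003021,0.816643,0.000377
UL,0.254614,0.033805,0.088867,0.062175,0.094781,0.465759
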