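class,area_1980,area_2020
AL,6138061,5780687
FO,4392590,4437070
GL,4572360,4426524
WA,176332,147680
CL,372407,863010
UL,14612,10870
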