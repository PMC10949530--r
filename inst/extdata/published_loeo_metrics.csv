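model,trait,predictor,unit,nrmse,cor
GBLUP,Yield,G,B2IR,0.2244,0.1151
DL,Yield,G,B2IR,0.2344,0.0688
GBLUP,Yield,E+G,B2IR,0.58,0.196
DL,Yield,E+G,B2IR,0.2226,0.2072
GBLUP,Yield,G,B5IR,0.3678,0.2025
DL,Yield,G,B5IR,0.3679,0.1323
GBLUP,Yield,E+G,B5IR,0.3757,0.2242
DL,Yield,E+G,B5IR,0.3679,0.2183
GBLUP,Yield,G,BDRT,0.3343,0.1682
DL,Yield,G,BDRT,0.3345,0.0444
GBLUP,Yield,E+G,BDRT,0.1183,0.2004
DL,Yield,E+G,BDRT,0.3366,0.1612
GBLUP,Yield,G,BLHT,0.1087,0.1979
DL,Yield,G,BLHT,0.108,-0.0262
GBLUP,Yield,E+G,BLHT,0.137,0.3071
DL,Yield,E+G,BLHT,0.1094,0.259
GBLUP,Maturity,G,B2IR,0.065,0.4312
DL,Maturity,G,B2IR,0.066,0.1832
GBLUP,Maturity,E+G,B2IR,0.1242,0.6294
DL,Maturity,E+G,B2IR,0.0614,0.6697
GBLUP,Maturity,G,B5IR,0.114,0.5775
DL,Maturity,G,B5IR,0.1133,0.6127
GBLUP,Maturity,E+G,B5IR,0.1092,0.5846
DL,Maturity,E+G,B5IR,0.1146,0.6216
GBLUP,Maturity,G,BDRT,0.0789,0.3197
DL,Maturity,G,BDRT,0.0801,0.2058
GBLUP,Maturity,E+G,BDRT,0.0307,0.5376
DL,Maturity,E+G,BDRT,0.076,0.6061
GBLUP,Height,G,B2IR,0.0482,0.2779
DL,Height,G,B2IR,0.0502,0.0721
GBLUP,Height,E+G,B2IR,0.0888,0.3433
DL,Height,E+G,B2IR,0.0482,0.29
GBLUP,Height,G,B5IR,0.1178,0.2243
DL,Height,G,B5IR,0.1171,0.1943
GBLUP,Height,E+G,B5IR,0.0873,0.2493
DL,Height,E+G,B5IR,0.1189,0.2629
GBLUP,Height,G,BDRT,0.1392,0.1805
DL,Height,G,BDRT,0.1392,0.0875
GBLUP,Height,E+G,BDRT,0.1047,0.2097
DL,Height,E+G,BDRT,0.1403,0.1894
GBLUP,Heading,G,B2IR,0.0708,0.5594
DL,Heading,G,B2IR,0.0754,0.5039
GBLUP,Heading,E+G,B2IR,0.1232,0.7642
DL,Heading,E+G,B2IR,0.0568,0.8158
GBLUP,Heading,G,B5IR,0.1197,0.7412
DL,Heading,G,B5IR,0.121,0.7732
GBLUP,Heading,E+G,B5IR,0.1097,0.7558
DL,Heading,E+G,B5IR,0.1202,0.7894
GBLUP,Heading,G,BDRT,0.097,0.4528
DL,Heading,G,BDRT,0.1051,0.4359
GBLUP,Heading,E+G,BDRT,0.0512,0.6449
DL,Heading,E+G,BDRT,0.0953,0.6551
GBLUP,Germination,G,B2IR,0.1004,0.0907
DL,Germination,G,B2IR,0.1012,0.0447
GBLUP,Germination,E+G,B2IR,0.0723,0.0895
DL,Germination,E+G,B2IR,0.1002,0.0352
GBLUP,Germination,G,B5IR,0.0735,0.0308
DL,Germination,G,B5IR,0.0726,0.0184
GBLUP,Germination,E+G,B5IR,0.0651,0.0314
DL,Germination,E+G,B5IR,0.073,0.0134
GBLUP,Germination,G,BDRT,0.1727,0.0685
DL,Germination,G,BDRT,0.1728,0.0357
GBLUP,Germination,E+G,BDRT,0.1823,0.068
DL,Germination,E+G,BDRT,0.169,0.1063
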