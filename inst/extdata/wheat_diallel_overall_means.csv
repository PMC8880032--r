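# Combined-environment adjusted means (2 locations x 2 years) of 18 spring
# bread wheat parents and 23 F1 hybrids from a 7-male x 11-female partial
# diallel: biomass (BM, t/ha), thousand kernel weight (TKW, g), grain yield (YLD, t/ha).
genotype,role,trait,estimate
P1,parent,BM,8.6
P2,parent,BM,7.42
P3,parent,BM,8.89
P4,parent,BM,7.77
P5,parent,BM,8.04
P6,parent,BM,7.65
P7,parent,BM,7.35
P8,parent,BM,8.22
P9,parent,BM,8.95
P10,parent,BM,8.97
P11,parent,BM,7.79
P12,parent,BM,7.58
P13,parent,BM,8.01
P14,parent,BM,8.12
P15,parent,BM,7.51
P16,parent,BM,8.32
P17,parent,BM,9
P18,parent,BM,8.5
P1,parent,TKW,36.49
P2,parent,TKW,34.1
P3,parent,TKW,35
P4,parent,TKW,34.71
P5,parent,TKW,35.72
P6,parent,TKW,34.7
P7,parent,TKW,34.56
P8,parent,TKW,34.83
P9,parent,TKW,38.77
P10,parent,TKW,37.62
P11,parent,TKW,36.93
P12,parent,TKW,37.8
P13,parent,TKW,35.97
P14,parent,TKW,35.95
P15,parent,TKW,33.98
P16,parent,TKW,36.99
P17,parent,TKW,34.53
P18,parent,TKW,36.42
P1,parent,YLD,4.25
P2,parent,YLD,4.08
P3,parent,YLD,3.93
P4,parent,YLD,4.26
P5,parent,YLD,4.19
P6,parent,YLD,4.07
P7,parent,YLD,3.88
P8,parent,YLD,4.39
P9,parent,YLD,4.24
P10,parent,YLD,4.25
P11,parent,YLD,4.17
P12,parent,YLD,4.11
P13,parent,YLD,4.32
P14,parent,YLD,3.92
P15,parent,YLD,3.97
P16,parent,YLD,4.14
P17,parent,YLD,4.23
P18,parent,YLD,4.29
P1/P2,hybrid,BM,8.35
P1/P6,hybrid,BM,8.57
P1/P8,hybrid,BM,8.79
P1/P18,hybrid,BM,8.32
P3/P2,hybrid,BM,8.02
P3/P6,hybrid,BM,9.08
P3/P8,hybrid,BM,7.9
P3/P18,hybrid,BM,8.51
P4/P7,hybrid,BM,7.14
P4/P11,hybrid,BM,7.75
P4/P17,hybrid,BM,8.11
P9/P2,hybrid,BM,9.28
P9/P6,hybrid,BM,8.9
P9/P8,hybrid,BM,8.69
P9/P18,hybrid,BM,9.13
P10/P5,hybrid,BM,9.06
P10/P12,hybrid,BM,9.48
P10/P14,hybrid,BM,8.94
P10/P15,hybrid,BM,8.93
P13/P7,hybrid,BM,7.9
P13/P11,hybrid,BM,8.58
P16/P7,hybrid,BM,8.15
P16/P11,hybrid,BM,8.32
P1/P2,hybrid,TKW,36.13
P1/P6,hybrid,TKW,38.84
P1/P8,hybrid,TKW,37.8
P1/P18,hybrid,TKW,36.11
P3/P2,hybrid,TKW,36.16
P3/P6,hybrid,TKW,35.48
P3/P8,hybrid,TKW,34.55
P3/P18,hybrid,TKW,35.03
P4/P7,hybrid,TKW,37.04
P4/P11,hybrid,TKW,36.62
P4/P17,hybrid,TKW,38.62
P9/P2,hybrid,TKW,39.36
P9/P6,hybrid,TKW,41.19
P9/P8,hybrid,TKW,40.59
P9/P18,hybrid,TKW,39.44
P10/P5,hybrid,TKW,39.81
P10/P12,hybrid,TKW,40.14
P10/P14,hybrid,TKW,40.78
P10/P15,hybrid,TKW,40.28
P13/P7,hybrid,TKW,35.16
P13/P11,hybrid,TKW,37.84
P16/P7,hybrid,TKW,32.79
P16/P11,hybrid,TKW,37.92
P1/P2,hybrid,YLD,4.21
P1/P6,hybrid,YLD,4.52
P1/P8,hybrid,YLD,4.37
P1/P18,hybrid,YLD,4.38
P3/P2,hybrid,YLD,4.04
P3/P6,hybrid,YLD,4.06
P3/P8,hybrid,YLD,4.17
P3/P18,hybrid,YLD,4.39
P4/P7,hybrid,YLD,4.65
P4/P11,hybrid,YLD,4.29
P4/P17,hybrid,YLD,4.73
P9/P2,hybrid,YLD,5.13
P9/P6,hybrid,YLD,5.27
P9/P8,hybrid,YLD,4.98
P9/P18,hybrid,YLD,4.7
P10/P5,hybrid,YLD,4.84
P10/P12,hybrid,YLD,4.72
P10/P14,hybrid,YLD,4.65
P10/P15,hybrid,YLD,4.58
P13/P7,hybrid,YLD,4.07
P13/P11,hybrid,YLD,4.19
P16/P7,hybrid,YLD,3.81
P16/P11,hybrid,YLD,4.04
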