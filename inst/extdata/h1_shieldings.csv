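system,nucleus,element,delta_exp_ppm,PBE,TPSS,B3LYP,DSD-PBEP86,MP2
l-alanine,H-a,H,3.82,26.91,27.28,27.23,27.23,27.09
l-alanine,NH3,H,8.50,22.15,22.57,22.25,22.18,22.04
l-alanine,H-b,H,1.38,29.43,29.81,29.67,29.63,29.52
a-glycine,NH3,H,8.48,22.35,22.81,22.46,22.39,22.25
a-glycine,H-a1,H,4.23,26.53,26.91,26.78,26.78,26.67
a-glycine,H-a2,H,3.06,27.51,27.90,27.79,27.79,27.69
l-serine,H-a,H,3.64,27.05,27.41,27.42,27.43,27.32
l-serine,H-b1,H,3.75,27.03,27.45,27.38,27.34,27.21
l-serine,H-b2,H,4.46,26.28,26.75,26.67,26.66,26.51
l-serine,NH3,H,8.37,22.37,22.84,22.50,22.43,22.30
l-serine,OH,H,3.79,27.49,27.89,27.55,27.34,27.10
l-aspartic acid,COOH,H,15.57,15.00,15.45,14.96,14.81,14.58
l-aspartic acid,H-b1,H,3.27,26.86,27.33,27.21,27.21,27.09
l-aspartic acid,H-b2,H,2.54,27.73,28.13,28.00,28.01,27.81
l-aspartic acid,NH3,H,8.32,22.70,23.11,22.82,22.80,22.63
l-aspartic acid,H-a,H,3.76,27.56,27.95,27.90,27.87,27.69
l-cysteine,H-b1,H,3.55,27.44,27.90,27.80,27.82,27.69
l-cysteine,H-b2,H,2.78,28.11,28.50,28.50,28.43,28.23
l-cysteine,H-a,H,4.28,26.74,27.13,27.10,27.14,27.00
l-cysteine,NH3,H,8.65,22.24,22.70,22.36,22.34,22.20
l-cysteine,SH,H,1.92,28.09,28.57,28.46,28.32,28.19
l-threonine,NH3,H,8.03,22.62,23.07,22.77,22.72,22.53
l-threonine,H-a,H,4.02,26.79,27.17,27.11,27.11,26.93
l-threonine,H-b,H,3.78,26.86,27.31,27.29,27.26,27.08
l-threonine,OH,H,7.95,22.39,22.84,22.44,22.31,22.17
l-threonine,H-g,H,1.39,29.53,29.92,29.78,29.69,29.59
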