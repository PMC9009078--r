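system,nucleus,element,delta_exp_ppm,PBE,TPSS,B3LYP,DSD-PBEP86,MP2
l-alanine,C-a,C,50.92,122.75,128.71,122.55,134.94,137.95
l-alanine,COO,C,177.71,-3.28,4.56,-8.58,7.33,12.23
l-alanine,C-b,C,20.36,154.14,160.50,154.46,165.91,169.45
a-glycine,COO,C,176.25,-1.78,5.92,-7.56,8.88,14.35
a-glycine,C-a,C,43.58,132.05,137.97,131.45,142.82,145.77
l-serine,C-a,C,55.69,118.11,124.76,118.04,130.21,132.84
l-serine,C-b,C,62.86,107.61,115.51,109.22,121.68,124.33
l-serine,COO,C,175.05,0.13,7.86,-5.01,10.60,16.04
l-aspartic acid,COO,C,175.91,-1.05,6.80,-6.28,10.43,16.14
l-aspartic acid,C-a,C,53.78,116.04,122.71,116.32,129.40,133.00
l-aspartic acid,C-b,C,37.77,137.49,145.01,137.91,149.58,153.27
l-aspartic acid,COOH,C,174.66,3.73,11.35,-0.88,15.57,19.18
l-cysteine,C-b,C,28.09,143.55,149.91,144.50,157.26,160.78
l-cysteine,C-a,C,56.01,117.45,123.82,117.45,129.65,132.15
l-cysteine,COO,C,173.37,0.39,8.07,-5.52,10.50,15.74
l-threonine,COO,C,172.06,-0.02,7.70,-5.85,10.90,16.65
l-threonine,C-a,C,61.25,111.19,118.34,111.34,123.75,126.31
l-threonine,C-b,C,66.93,102.23,109.40,103.91,116.63,118.81
l-threonine,C-g,C,20.48,155.13,161.52,155.00,165.77,169.34
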