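cross,generation,n,min,max,mean,sd,variance,cv_percent
crossA,P1,50,125.02,160.02,141.24,8.27,68.37,5.85
crossA,P2,50,62.76,90.27,78.58,7.26,52.64,9.23
crossA,F1,46,96.64,135.68,112.22,10.22,104.54,9.11
crossA,F2,217,57.70,163.86,101.00,20.27,410.95,20.07
crossA,BC1P1,128,78.25,181.67,125.52,23.17,536.94,18.46
crossA,BC1P2,123,55.30,118.36,87.40,14.76,217.78,16.89
crossB,P1,50,122.79,154.89,139.34,9.15,83.73,6.57
crossB,P2,50,62.75,89.02,74.30,7.30,53.24,9.82
crossB,F1,48,99.74,129.13,112.94,8.26,68.20,7.31
crossB,F2,245,47.23,174.65,94.37,23.64,558.84,25.05
crossB,BC1P1,119,85.32,170.50,122.81,19.77,390.70,16.09
crossB,BC1P2,111,54.54,123.66,87.81,16.96,287.71,19.32
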