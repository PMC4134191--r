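tumor_id,status,marker,mean,sd,cv
T1,positive,HIF-1a,123.72,27.78,0.22
T1,positive,LDH-M,134.17,10.75,0.08
T1,positive,CAIX,97.40,31.83,0.33
T1,positive,ATP5b,66.26,12.60,0.19
T2,positive,HIF-1a,69.23,15.78,0.23
T2,positive,LDH-M,148.74,8.73,0.06
T2,positive,CAIX,138.65,43.32,0.31
T2,positive,ATP5b,51.20,11.42,0.22
T3,negative,HIF-1a,79.30,11.60,0.15
T3,negative,LDH-M,151.01,7.38,0.05
T3,negative,CAIX,170.69,14.65,0.09
T3,negative,ATP5b,79.9,6.07,0.08
T4,negative,HIF-1a,90.73,17.37,0.19
T4,negative,LDH-M,156.80,6.89,0.04
T4,negative,CAIX,151.01,7.38,0.05
T4,negative,ATP5b,85.02,10.06,0.12
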