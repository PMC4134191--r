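patient,volume_mL,max,min,mean,median,sd,cv
1,3.19,287489.06,174075.95,246704.23,249721.62,27098.21,0.12
2,66.86,456195.81,155267.7,333665.19,333957.66,50224.01,0.15
3,36.15,261265.5,33070.44,148666.3,142562.28,52314.15,0.37
4,5.18,620795.06,371847.78,542301.38,544443.94,50281.7,0.09
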