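landmark,rmse_mm,mape_pct
MRD1,0.261,10.7
MRD2,0.283,6.26
MBE,4.42,1.78
ML,4.66,1.85
PC,2.22,1.81
LL,2.75,2.81
LBE,2.75,2.79
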