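variable,range,category,n,mortality_pct,or,or_lo,or_hi,p_trend
age,<47,1,72,26.4,1,NA,NA,0.0046
age,47-66,2,196,43.9,2.18,1.2,3.95,NA
age,>66,3,171,48,2.57,1.41,4.7,NA
pf_ratio,>158,1,239,36.4,1,NA,NA,0.0015
pf_ratio,105-158,2,135,46.7,1.53,1,2.35,NA
pf_ratio,<105,3,65,56.9,2.31,1.32,4.03,NA
pmax,<27,1,233,34.8,1,NA,NA,0.0021
pmax,27-30,2,48,25,0.63,0.31,1.27,NA
pmax,>33,3,134,52.2,2.05,1.33,3.17,NA
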