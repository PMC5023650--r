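variable,range,category,n,mortality_pct,or,or_lo,or_hi,p_trend
age,<47,1,72,26.4,1,NA,NA,0.0021
age,47-59,2,96,41.7,1.99,1.03,3.87,NA
age,>59,3,271,47.2,2.5,1.4,4.44,NA
pf_ratio,>158,1,239,36.4,1,NA,NA,0.0015
pf_ratio,105-158,2,135,46.7,1.53,1,2.35,NA
pf_ratio,<105,3,65,56.9,2.31,1.32,4.03,NA
pmax,<30,1,281,33.1,1,NA,NA,0.0001
pmax,30-33,2,40,45,1.65,0.85,3.23,NA
pmax,>33,3,94,55.3,2.5,1.55,4.03,NA
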