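service,arbitration_style,total_women,included,normal,all_cancers,screen_detected,interval_cancers,next_screen_detected,recall_rate_pct,arbitration_rate_pct,direct_to_clinic_pct,cdr_per_1000
all,mixed,125000,115973,113972,2001,876,336,789,4.0,NA,NA,8.03
1,discordant_only,25000,23023,22674,349,169,68,112,4.9,3.9,3.2,8.84
2,arbitrate_all,25000,22630,22248,382,191,68,123,4.4,12.1,NA,7.60
3,discordant_only,25000,23400,23004,396,178,64,154,4.0,2.7,3.1,8.12
4,discordant_only,25000,23590,23135,455,186,65,204,3.2,3.4,2.3,8.48
5,arbitrate_all,25000,23330,22911,419,152,71,196,3.3,5.6,NA,7.12
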