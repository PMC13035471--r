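reader,recall_rate_pct,cdr_per_1000
ai,7.1,10.0
reader1,11.8,9.19
consensus,8.5,NA
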