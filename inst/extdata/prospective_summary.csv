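service,all_cases,included_cases,period1_initial_op,period2_adjusted_op,normal,screen_detected
1,3566,3220,1358,1862,3197,23
2,7312,6046,2320,3726,5996,50
both,10878,9266,3678,5588,9193,73
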