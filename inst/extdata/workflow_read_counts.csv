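arm,screening_reads,arbitration_reads
human_plus_ai,133943,12408
human_double,249916,7740
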