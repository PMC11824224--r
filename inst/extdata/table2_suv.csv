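group,region,statistic,mean,sd,n
knockout,muscle,SUVpeak,0.0539037,0.021831,3
knockout,right_parotid,SUVpeak,0.0935844,0.0024531,3
knockout,left_parotid,SUVpeak,0.0899706,0.007456,3
wild_type,muscle,SUVpeak,0.1513213,0.077567,3
wild_type,right_parotid,SUVpeak,0.22119358,0.0404992,3
wild_type,left_parotid,SUVpeak,0.2467296,0.0525369,3
knockout,muscle,SUVmax,0.0592641,0.023289,3
knockout,right_parotid,SUVmax,0.10068921,0.0015846,3
knockout,left_parotid,SUVmax,0.0993156,0.0097529,3
wild_type,muscle,SUVmax,0.1604765,0.076283,3
wild_type,right_parotid,SUVmax,0.23704056,0.0411132,3
wild_type,left_parotid,SUVmax,0.2627125,0.0512088,3
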