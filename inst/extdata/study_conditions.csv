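condition,atp_mM,pi_mM,f0_kpa,sem_kpa
Baseline,5,1,21.800000000000001,2.1000000000000001
Low ATP,1,1,27.699999999999999,3.1000000000000001
Super-low ATP,0.10000000000000001,1,32.299999999999997,2.3999999999999999
No Pi,5,0,25.5,2.8999999999999999
High Pi,5,5,18,1.6000000000000001
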