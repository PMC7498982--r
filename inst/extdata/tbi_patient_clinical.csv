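patient,trauma_mechanism,gcs,iss,ventilation_days,gose_1y,pta_days
P01,traffic,4,24,12,6,76
P02,fall,3,35,33,3,221
P03,uncertain,6,25,14,4,356
P04,traffic,3,30,39,3,365
P05,traffic,3,59,25,NA,NA
P06,traffic,3,27,29,7,77
P07,fall,3,16,20,3,199
P08,fall,8,31,29,4,62
P09,traffic,4,33,20,4,104
P10,traffic,3,34,16,4,330
P11,traffic,6,27,27,4,286
P12,traffic,3,43,15,6,102
P13,traffic,7,24,13,3,86
P14,traffic,3,43,18,6,212
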