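sample,group,dose_mM,target_ct,ref_ct
c1,control,0,25.12,20.03
c2,control,0,24.95,19.92
c3,control,0,25.08,20.11
d1a,mms_0.1,0.1,24.31,20.05
d1b,mms_0.1,0.1,24.22,19.96
d1c,mms_0.1,0.1,24.40,20.08
d2a,mms_0.25,0.25,23.44,20.02
d2b,mms_0.25,0.25,23.52,20.10
d2c,mms_0.25,0.25,23.35,19.95
d3a,mms_0.5,0.5,22.28,20.01
d3b,mms_0.5,0.5,22.41,20.06
d3c,mms_0.5,0.5,22.20,19.93
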