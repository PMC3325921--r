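cell_id,group,dose_mM,tail_length_um,pct_dna_in_tail
1,control,0,6.1,8.2
2,control,0,4.8,6.5
3,control,0,7.3,9.1
4,control,0,5.5,7.4
5,control,0,6.6,8.8
6,mms_0.1,0.1,15.2,18.5
7,mms_0.1,0.1,13.8,16.2
8,mms_0.1,0.1,16.9,20.3
9,mms_0.1,0.1,14.5,17.8
10,mms_0.1,0.1,15.8,19.0
11,mms_0.25,0.25,26.4,30.1
12,mms_0.25,0.25,24.1,27.5
13,mms_0.25,0.25,28.0,33.2
14,mms_0.25,0.25,25.3,29.4
15,mms_0.25,0.25,27.1,31.6
16,mms_0.5,0.5,38.6,44.8
17,mms_0.5,0.5,35.9,41.2
18,mms_0.5,0.5,40.7,47.5
19,mms_0.5,0.5,37.4,43.0
20,mms_0.5,0.5,39.5,45.9
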