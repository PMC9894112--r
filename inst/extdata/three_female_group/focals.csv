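focal_id,subject_id,group,year,duration_s
A_f1,A,1,1,1000
B_f1,B,1,1,1000
C_f1,C,1,1,1000
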