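focal_id,scan_index,subject_id,neighbor_id
A_f1,1,A,B
A_f1,2,A,B
A_f1,3,A,B
A_f1,4,A,B
A_f1,5,A,B
A_f1,6,A,B
A_f1,7,A,C
A_f1,8,A,C
A_f1,9,A,C
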