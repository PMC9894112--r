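focal_id,actor_id,receiver_id,duration_s
A_f1,A,B,100
B_f1,B,C,50
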