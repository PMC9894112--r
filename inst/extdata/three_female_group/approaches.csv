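focal_id,actor_id,receiver_id
A_f1,A,B
B_f1,B,A
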