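group,year,winner_id,loser_id
1,1,A,B
1,1,A,C
1,1,B,C
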