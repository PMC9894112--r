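id,sex,birth_year,death_year,mother_id
A,F,-10,,
B,F,-12,,
C,F,-14,,
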