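id,sex,birth_year,death_year,mother_id,father_id
GM,F,0,,,
F1,M,0,,,
M2,M,0,,,
M3,M,0,,,
M4,M,0,,,
U,F,0,,,
X,F,0,,,
Y,F,0,,,
Z,F,0,,,
A,F,5,,GM,F1
B,F,5,,GM,F1
C,F,6,,GM,M2
D,F,10,,A,M3
E,F,10,,B,M4
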