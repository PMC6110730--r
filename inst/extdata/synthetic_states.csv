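species,state
t01,1
t02,1
t03,0
t04,0
t05,0
t06,1
t07,0
t08,0
t09,0
t10,0
t11,0
t12,0
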