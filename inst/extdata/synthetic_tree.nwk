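(((t01:1.2,t02:1.2):2.1,((t03:0.9,t04:0.9):1.0,t05:1.9):1.4):2.7,((t06:1.5,(t07:0.7,t08:0.7):0.8):1.6,((t09:1.1,t10:1.1):0.9,(t11:0.6,t12:0.6):1.4):1.1):2.9);
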