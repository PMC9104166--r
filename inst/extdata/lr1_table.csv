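bin,lr1
<0.32,0.1
0.32-0.42,0.4
0.43-0.53,0.8
0.54-0.64,1.7
>=0.65,25
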