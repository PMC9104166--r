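name: scheme1
co2: 1000.0
co: 8.7
rsp: 180.0
no2: 150.0
o3: 120.0
hcho: 100.0
tvoc: 600.0
radon: 200.0
abc: 1000.0
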