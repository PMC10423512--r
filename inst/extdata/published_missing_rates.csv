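variable,rate
bmi,0.563
smoking,0.244
tc,0.717
tg,0.807
ldl,0.856
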