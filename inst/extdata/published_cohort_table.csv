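category,n,pct
<120,3943,10.0
120-129,5870,14.8
130-139,8097,20.4
140-149,9050,22.9
150-159,6101,15.4
>=160,6541,16.5
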