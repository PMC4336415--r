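level_id,certified_value,U_crm
f,10,1.5
e,104,10
d,1020,90
c,10300,1000
b,108000,11000
a,1080000,130000
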